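# shared fixture builders (everything generated in code, fixed seeds)

full_grid <- function(n_side) {
  as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side)))
}

# random irregular subset of a square grid
ragged_grid <- function(n_side, n_keep, seed = 1) {
  co <- full_grid(n_side)
  set.seed(seed)
  co[sample(nrow(co), n_keep), , drop = FALSE]
}

# nested 2x2 block-average oracle for the haar smooth component
block_average <- function(m, level) {
  s <- 2L^level
  n <- nrow(m)
  out <- m
  for (i in seq(1, n, by = s)) for (j in seq(1, n, by = s)) {
    blk <- m[i:(i + s - 1L), j:(j + s - 1L)]
    out[i:(i + s - 1L), j:(j + s - 1L)] <- mean(blk)
  }
  out
}

# textbook unweighted Cohen's kappa on a 2x2 split at threshold t
kappa_oracle <- function(actuals, predictions, t) {
  pa <- as.integer(predictions >= t)
  po <- mean(actuals == pa)
  pe <- mean(actuals) * mean(pa) + mean(1 - actuals) * mean(1 - pa)
  (po - pe) / (1 - pe)
}

# Mann-Whitney rank AUC with 0.5 credit for ties
auc_oracle <- function(actuals, predictions) {
  r <- rank(predictions)
  n1 <- sum(actuals == 1); n0 <- sum(actuals == 0)
  (sum(r[actuals == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# independent re-statement of the hierarchy rule for the property test
removable_set <- function(labels) {
  out <- character(0)
  for (t in labels) {
    tv <- all.vars(as.formula(paste("~", t)))
    others <- setdiff(labels, t)
    blocked <- FALSE
    for (u in others) {
      uv <- all.vars(as.formula(paste("~", u)))
      if (length(tv) == 1L && t == tv && tv %in% uv) blocked <- TRUE
      if (t != tv[1] && all(tv %in% uv) && length(uv) > length(tv))
        blocked <- TRUE
    }
    if (!blocked) out <- c(out, t)
  }
  out
}

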