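# Independent LP oracle: exhaustive enumeration of basic solutions
# (vertices) of {A x = b, lb <= x <= ub}. Deliberately avoids the package's
# simplex; uses dense QR least squares only. Only suitable for networks
# with around a dozen reactions.

oracle_lp <- function(obj, A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  k <- n - r
  best <- -Inf
  best_x <- NULL
  subsets <- utils::combn(n, k, simplify = FALSE)
  if (k == 0L) subsets <- list(integer(0))
  for (N in subsets) {
    Bcols <- setdiff(seq_len(n), N)
    AB <- A[, Bcols, drop = FALSE]
    qrB <- qr(AB)
    if (qrB$rank < length(Bcols)) next
    if (k > 0) {
      grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
      XN <- matrix(0, k, nrow(grid))
      for (i in seq_len(k))
        XN[i, ] <- ifelse(grid[, i], ub[N[i]], lb[N[i]])
      RHS <- b - A[, N, drop = FALSE] %*% XN
    } else {
      XN <- matrix(0, 0, 1)
      RHS <- matrix(b, ncol = 1)
    }
    XB <- qr.coef(qrB, RHS)
    resid <- AB %*% XB + (if (k > 0) A[, N, drop = FALSE] %*% XN else 0) - b
    for (col in seq_len(ncol(XB))) {
      xb <- XB[, col]
      if (anyNA(xb)) next
      if (max(abs(resid[, col])) > tol) next
      if (any(xb < lb[Bcols] - tol) || any(xb > ub[Bcols] + tol)) next
      x <- numeric(n)
      x[Bcols] <- xb
      if (k > 0) x[N] <- XN[, col]
      val <- sum(obj * x)
      if (val > best) { best <- val; best_x <- x }
    }
  }
  if (is.null(best_x)) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best, x = best_x)
}

oracle_fba <- function(model, objective = model$biomass_reaction,
                       sense = "max") {
  S <- as.matrix(stoichiometric_matrix(model))
  obj <- numeric(ncol(S))
  obj[match(objective, model$reactions$id)] <- if (sense == "max") 1 else -1
  res <- oracle_lp(obj, S, rep(0, nrow(S)),
                   model$reactions$lower_bound, model$reactions$upper_bound)
  if (res$status == "optimal" && sense == "min")
    res$objective <- -res$objective
  res
}

# lexicographic oracle: stage optima via re-enumeration with each previous
# stage's objective appended as an equality row
oracle_lex <- function(model, stages) {
  S <- as.matrix(stoichiometric_matrix(model))
  b <- rep(0, nrow(S))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  optima <- numeric(length(stages))
  for (s in seq_along(stages)) {
    idx <- match(stages[[s]][1], model$reactions$id)
    sgn <- if (stages[[s]][2] == "max") 1 else -1
    obj <- numeric(ncol(S)); obj[idx] <- sgn
    res <- oracle_lp(obj, S, b, lb, ub)
    if (res$status != "optimal") return(NULL)
    optima[s] <- sgn * res$objective
    row <- numeric(ncol(S)); row[idx] <- 1
    S <- rbind(S, row)
    b <- c(b, optima[s])
  }
  optima
}
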