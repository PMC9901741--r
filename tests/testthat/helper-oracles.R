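# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and enumeration only.

# Full scaling chain oracle: score matrix (samples x cell types, log2 scale)
# -> list(scaled, A, I, ratio). Direct loops over Eq-style arithmetic.
oracle_profile <- function(scores, panel) {
  n <- nrow(scores)
  types <- colnames(scores)
  linear <- matrix(NA_real_, n, length(types), dimnames = dimnames(scores))
  for (i in seq_len(n)) for (j in seq_along(types)) {
    linear[i, j] <- 2^scores[i, j] - 1
  }
  scaled <- linear
  for (j in seq_along(types)) {
    lo <- min(linear[, j]); hi <- max(linear[, j])
    for (i in seq_len(n)) {
      scaled[i, j] <- if (hi == lo) 0 else (linear[i, j] - lo) / (hi - lo)
    }
  }
  comp <- setNames(panel$compartment[match(types, panel$cell_type)], types)
  A <- I <- numeric(n)
  for (i in seq_len(n)) {
    A[i] <- mean(scaled[i, comp == "adaptive"])
    I[i] <- mean(scaled[i, comp == "innate"])
  }
  ratio <- ifelse(I == 0, NA_real_, A / I)
  list(scaled = scaled, A = A, I = I, ratio = ratio)
}

# Sort-based tie-averaged ranking oracle (lowest value -> rank 1).
oracle_rank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  pos <- 1
  while (pos <= length(x)) {
    end <- pos
    while (end < length(x) && x[ord[end + 1]] == x[ord[pos]]) end <- end + 1
    r[ord[pos:end]] <- mean(pos:end)
    pos <- end + 1
  }
  r
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_wilcoxon_exact <- function(x, y) {
  values <- c(x, y)
  n1 <- length(x)
  r <- rank(values)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(values), n1)
  w_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided Fisher exact p by hypergeometric enumeration
# (point-probability method: sum of table probabilities <= observed).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Inverse-variance fixed-effect combination, spreadsheet-style arithmetic.
oracle_meta <- function(loghr, se) {
  w <- 1 / se^2
  est <- sum(w * loghr) / sum(w)
  list(est = est, se = sqrt(1 / sum(w)), hr = exp(est))
}

# Direct partial-likelihood maximisation for a single covariate with all
# distinct event times (no ties): numerical oracle for coxph.
oracle_cox1 <- function(time, event, x) {
  nll <- function(b) {
    ord <- order(time)
    t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord]
    ll <- 0
    for (i in seq_along(t_s)) {
      if (e_s[i] == 1) {
        risk <- which(t_s >= t_s[i])
        ll <- ll + b * x_s[i] - log(sum(exp(b * x_s[risk])))
      }
    }
    -ll
  }
  stats::optimize(nll, c(-20, 20), tol = 1e-10)$minimum
}
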