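# Independent reference implementations used only to cross-check the package.

# Brute-force maze scorer: explicit pairwise comparisons over a matrix of
# entry sequences (rows = entry position, cols = sequences). No shared code
# with the package path (which uses hashing/duplicated on long tables).
oracle_score_matrix <- function(seq_mat, baited) {
  L <- nrow(seq_mat)
  n <- ncol(seq_mat)
  dup <- matrix(FALSE, L, n)
  if (L > 1) {
    for (i in 2:L) {
      seen <- matrix(FALSE, 1, n)
      for (j in 1:(i - 1)) {
        seen <- seen | (seq_mat[j, , drop = FALSE] == seq_mat[i, , drop = FALSE])
      }
      dup[i, ] <- seen
    }
  }
  unb <- matrix(!(seq_mat %in% baited), L, n)
  list(
    wme = as.integer(colSums(dup)),
    rme = as.integer(colSums(!dup & unb))
  )
}

# Plain-loop scorer for single runs (a second, even simpler formulation)
oracle_score_run <- function(entries, baited) {
  visited <- integer(0)
  rme <- 0L
  wme <- 0L
  for (a in entries) {
    if (a %in% visited) {
      wme <- wme + 1L
    } else if (!(a %in% baited)) {
      rme <- rme + 1L
    }
    visited <- c(visited, a)
  }
  list(rme = rme, wme = wme)
}

# All sequences of length L over arms 1..n_arms, as an L x n_arms^L matrix
all_sequences <- function(L, n_arms = 8) {
  n <- n_arms^L
  idx <- 0:(n - 1)
  m <- matrix(0L, L, n)
  for (i in 1:L) {
    m[i, ] <- (idx %/% n_arms^(i - 1)) %% n_arms + 1L
  }
  m
}

# All valid baited sets (4 of n_arms, no three circularly adjacent)
all_valid_baited_sets <- function(n_arms = 8) {
  combos <- utils::combn(n_arms, 4)
  valid <- apply(combos, 2, function(s) {
    m <- logical(n_arms)
    m[s] <- TRUE
    nxt <- function(i) (i %% n_arms) + 1L
    !any(vapply(seq_len(n_arms),
                function(i) m[i] && m[nxt(i)] && m[nxt(nxt(i))], TRUE))
  })
  combos[, valid, drop = FALSE]
}

# Monte-Carlo permutation two-sided p-value for the Mann-Whitney U
perm_mwu_p <- function(x, y, n_resample = 1e5) {
  n1 <- length(x)
  pooled <- rank(c(x, y))
  u_from_r1 <- function(r1) sum(r1) - n1 * (n1 + 1) / 2
  u_obs <- u_from_r1(pooled[seq_len(n1)])
  mu <- n1 * length(y) / 2
  dev_obs <- abs(u_obs - mu)
  devs <- vapply(seq_len(n_resample), function(b) {
    abs(u_from_r1(sample(pooled, n1)) - mu)
  }, numeric(1))
  mean(devs >= dev_obs - 1e-9)
}

# One-way repeated-measures ANOVA F for the within factor, by the sums of
# squares formulas (subjects x conditions, complete balanced table)
oracle_rm_oneway <- function(mat) { # rows = subjects, cols = conditions
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# small default cohort for fast end-to-end tests
tiny_cohort_config <- function(seed = 42, ...) {
  cohort_config(
    n_deaf = 3, n_control = 3, seed = seed,
    epoch_duration = 20,
    units_per_animal = list(mpfc = c(control = 6, deaf = 6),
                            ic = c(control = 4, deaf = 4)),
    maze = list(
      control = list(n_runs = 12, p_rme = 0.45, p_wme = 0.25,
                     learning_decay = 0.75),
      deaf = list(n_runs = 12, p_rme = 0.6, p_wme = 0.4,
                  learning_decay = 0.8)
    ),
    ...
  )
}
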