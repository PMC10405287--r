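# Independent oracles and small fixtures shared across tests.

# small-cohort config for fast trial-level runs
small_config <- function(n = 12L, seed = 101L, ...) {
  ef_config(n_per_cohort = c(G34 = n, G56 = n, G78 = n), seed = seed, ...)
}

# a one-row student profile with abilities set directly
profile_with <- function(ability = 0, speed = 450, cohort = "G34",
                         growth = 0.02) {
  tibble::tibble(
    student_id = "S1", cohort = cohort, gender = "male",
    school_id = "school_01", age_months_at_entry = 100,
    colorblind = FALSE, speed = speed,
    g = ability, wm = ability, cm = ability, ir = ability,
    growth = growth
  )
}

battery_spec <- function(task_name, config = ef_config()) {
  b <- task_battery(config)
  b[b$task == task_name, ]
}

# --- exhaustive set-partition oracle for 8-node spinglass ------------------

# all set partitions of n labeled nodes as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_label) {
    if (length(assign) == n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (k in seq_len(next_label)) {
      rec(c(assign, k - 1L), max(next_label, k + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# independent Hamiltonian evaluation (own arithmetic, not the package's):
# builds the signed modularity-style coupling and scores every partition at
# once through a precomputed same-community indicator matrix
exhaustive_min_hamiltonian <- local({
  cache <- new.env()
  function(w, gamma_pos = 1, gamma_neg = 1) {
    n <- nrow(w)
    key <- paste0("n", n)
    if (is.null(cache[[key]])) {
      parts <- all_partitions(n)
      pm <- do.call(rbind, parts)
      pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
      same <- matrix(0L, nrow(pm), nrow(pairs))
      for (e in seq_len(nrow(pairs))) {
        same[, e] <- as.integer(pm[, pairs[e, 1L]] == pm[, pairs[e, 2L]])
      }
      cache[[key]] <- list(pm = pm, pairs = pairs, same = same)
    }
    cx <- cache[[key]]
    wp <- pmax(w, 0); diag(wp) <- 0
    wn <- pmax(-w, 0); diag(wn) <- 0
    sp <- rowSums(wp); sn <- rowSums(wn)
    mp <- sum(wp) / 2; mn <- sum(wn) / 2
    a_full <- wp - wn
    if (mp > 0) a_full <- a_full - gamma_pos * tcrossprod(sp) / (2 * mp)
    if (mn > 0) a_full <- a_full + gamma_neg * tcrossprod(sn) / (2 * mn)
    a_vec <- a_full[cx$pairs]
    h <- -as.vector(cx$same %*% a_vec)
    list(min = min(h), argmin = cx$pm[which.min(h), ], all = h)
  }
})

# closed-form ML moments for bivariate monotone missingness (regression /
# sweep estimator): x fully observed, y observed on the first nc rows
monotone_ml_moments <- function(x, y_obs) {
  n <- length(x)
  nc <- length(y_obs)
  xc <- x[seq_len(nc)]
  mx <- mean(x)
  sxx <- mean((x - mx)^2)
  mxc <- mean(xc)
  myc <- mean(y_obs)
  sxx_c <- mean((xc - mxc)^2)
  sxy_c <- mean((xc - mxc) * (y_obs - myc))
  syy_c <- mean((y_obs - myc)^2)
  b <- sxy_c / sxx_c
  se <- syy_c - b * sxy_c
  my <- myc + b * (mx - mxc)
  sxy <- b * sxx
  syy <- se + b^2 * sxx
  list(mean = c(mx, my),
       cov = matrix(c(sxx, sxy, sxy, syy), 2, 2))
}

expect_tibble <- function(x) {
  expect_s3_class(x, "tbl_df")
}
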