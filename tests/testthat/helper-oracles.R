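# Shared fixtures and independent oracles used across the suite.

# Small, fast simulation configuration for unit tests (the full-size
# defaults are exercised in the acceptance tests).
tiny_config <- function(...) {
  args <- list(n_subjects = 4, n_channels = 8, sampling_rate = 100)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Brute-force within-subject (repeated-measures) ANOVA by explicit
# sums of squares, independent of stats::aov and of the package's
# closed-form contrasts.  `y` is a numeric response, `factors` a data
# frame of within-subject factors, `subject` a factor.  Each effect's F is
# MS(effect) / MS(effect x subject), computed by inclusion-exclusion of
# cell means.
brute_rm_anova <- function(y, factors, subject) {
  dat <- cbind(factors, .subject = subject)
  dat[] <- lapply(dat, as.factor)
  n_levels <- vapply(dat, nlevels, integer(1L))
  all_names <- names(dat)
  # effect deviations by recursion: dev(T) = marginal mean over T's cells
  # minus the grand mean minus every lower-order deviation
  dev_cache <- list()
  dev_of <- function(T_set) {
    T_set <- sort(T_set)
    key <- paste(T_set, collapse = ":")
    if (!is.null(dev_cache[[key]])) return(dev_cache[[key]])
    mu <- tapply(y, dat[T_set], mean)
    grid <- expand.grid(dimnames(mu), stringsAsFactors = FALSE)
    names(grid) <- T_set
    mu_vec <- as.vector(mu)          # expand.grid order matches array order
    adj <- rep(mean(y), nrow(grid))
    if (length(T_set) > 1L) {
      subs <- unlist(lapply(seq_len(length(T_set) - 1L), function(m)
        utils::combn(T_set, m, simplify = FALSE)), recursive = FALSE)
      for (U in subs) {
        dU <- dev_of(U)
        key_g <- do.call(paste, c(grid[U], sep = "\r"))
        key_u <- do.call(paste, c(dU$grid, sep = "\r"))
        adj <- adj + dU$dev[match(key_g, key_u)]
      }
    }
    res <- list(grid = grid, dev = mu_vec - adj)
    dev_cache[[key]] <<- res
    res
  }
  ss_of <- function(T_set) {
    d <- dev_of(T_set)
    mult <- prod(n_levels[setdiff(all_names, T_set)])
    mult * sum(d$dev^2)
  }
  df_of <- function(T_set) prod(n_levels[T_set] - 1L)

  within <- setdiff(all_names, ".subject")
  effects <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  out <- lapply(effects, function(E) {
    err <- c(E, ".subject")
    Fv <- (ss_of(E) / df_of(E)) / (ss_of(err) / df_of(err))
    data.frame(effect = paste(E, collapse = ":"), F = Fv,
               df = df_of(E), df_error = df_of(err),
               p = stats::pf(Fv, df_of(E), df_of(err), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Match recovered template maps to planted ones by absolute spatial
# correlation; returns for each truth map the best |r| and which recovered
# map attains it.
match_templates <- function(truth, recovered) {
  cc <- crossprod(apply(truth, 2L, function(v) (v - mean(v)) /
                          sqrt(mean((v - mean(v))^2))),
                  apply(recovered, 2L, function(v) (v - mean(v)) /
                          sqrt(mean((v - mean(v))^2)))) / nrow(truth)
  list(best = apply(abs(cc), 1L, max),
       index = apply(abs(cc), 1L, which.max),
       cc = cc)
}

# Tiny hand-built ERP dataset: deterministic values, all 8 conditions.
toy_dataset <- function(n_channels = 4, n_time = 10, n_subjects = 3,
                        sampling_rate = 1000, fill = NULL) {
  conds <- condition_grid()$condition
  subjects <- sprintf("S%d", seq_len(n_subjects))
  data <- array(seq_len(n_channels * n_time * n_subjects * length(conds)) %% 7,
                dim = c(n_channels, n_time, n_subjects, length(conds)),
                dimnames = list(sprintf("c%d", seq_len(n_channels)), NULL,
                                subjects, conds))
  if (!is.null(fill)) data[] <- fill
  erp_dataset(data, sampling_rate,
              c(0, n_time * 1000 / sampling_rate),
              affected_side = stats::setNames(
                rep(c("left", "right"), length.out = n_subjects), subjects))
}
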