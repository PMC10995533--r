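# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately take the slow, literal route so they stay
# independent of the package's implementations.

# Exact two-sided rank-sum p-value by bitmask enumeration of every
# assignment of pooled observations to the first sample.
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  mu <- na * (N + 1) / 2
  obs_dev <- abs(sum(r[seq_len(na)]) - mu)
  cnt <- 0L
  tot <- 0L
  for (mask in 0:(2^N - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(N - 1)), 1L)
    if (sum(bits) == na) {
      tot <- tot + 1L
      if (abs(sum(r[bits == 1L]) - mu) >= obs_dev - 1e-12) cnt <- cnt + 1L
    }
  }
  cnt / tot
}

# Tie-corrected Kruskal-Wallis H from its textbook definition.
oracle_kw_H <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  gi <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, gi, mean)
  H0 <- 12 / (N * (N + 1)) *
    sum(lengths(groups) * (rbar - (N + 1) / 2)^2)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) 0 else H0 / corr
}

# Exhaustive check of the compact-letter-display biconditional:
# two groups share a letter <=> their pair is not significant.
cld_consistent <- function(letters_by_group, pairwise) {
  for (i in seq_len(nrow(pairwise))) {
    li <- strsplit(letters_by_group[[pairwise$group1[i]]], "")[[1]]
    lj <- strsplit(letters_by_group[[pairwise$group2[i]]], "")[[1]]
    share <- length(intersect(li, lj)) > 0
    if (share == pairwise$significant[i]) return(FALSE)
  }
  TRUE
}

# Small hand-buildable record sets.
make_record <- function(night, hut, arm, trapped = 0, dead = 0,
                        delayed = 0, survived = 0,
                        species = "an_gambiae", sleeper = hut) {
  data.frame(night = night, hut = hut, sleeper = sleeper, arm = arm,
             species_group = species, trapped = trapped,
             dead_untrapped = dead, alive_delayed_dead = delayed,
             alive_survived = survived, stringsAsFactors = FALSE)
}

random_records <- function(n, n_arms = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arms <- paste0("arm", seq_len(n_arms))
  grid <- expand.grid(night = 1:20, hut = 1:10,
                      species_group = c("an_gambiae", "other"),
                      stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid), n), ]
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(grid$night[i], grid$hut[i], sample(arms, 1),
                trapped = rpois(1, 1), dead = rpois(1, 2),
                delayed = rpois(1, 1), survived = rpois(1, 3),
                species = grid$species_group[i])
  }))
}

# Delta-method standard error of the control-adjusted killing effect
# estimated from per-hut-night kill/entry sums of three independent arms.
killing_effect_mc_se <- function(kill_cand, kill_ref, entry_un) {
  Kc <- sum(kill_cand); Kr <- sum(kill_ref); Tu <- sum(entry_un)
  vK <- function(x) length(x) * stats::var(x)
  ke <- 100 * (Kc - Kr) / Tu
  sqrt((100 / Tu)^2 * (vK(kill_cand) + vK(kill_ref)) +
         (ke / Tu)^2 * vK(entry_un))
}
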