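# Nonparametric inference used for hut-trial endpoints: Kruskal-Wallis
# across arms, Conover-Iman rank-based pairwise comparisons with
# Bonferroni correction, two-sample rank-sum tests, and compact letter
# displays for summary tables.

as_grouped <- function(x, g = NULL) {
  if (is.list(x) && is.null(g)) {
    groups <- names(x) %||% paste0("g", seq_along(x))
    x <- lapply(x, as.numeric)
    names(x) <- groups
  } else {
    if (length(x) != length(g)) {
      stop("`x` and `g` must have equal length", call. = FALSE)
    }
    x <- split(as.numeric(x), factor(g, levels = unique(g)))
  }
  if (length(x) < 2L) {
    stop("invalid input: need at least two groups", call. = FALSE)
  }
  sizes <- lengths(x)
  if (any(sizes == 0L)) {
    stop("invalid input: empty group(s): ",
         paste(names(x)[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  x
}

#' Kruskal-Wallis rank test across arms
#'
#' Compares the distribution of per-hut-night values (entries or deaths)
#' across treatment arms. Mid-ranks are used for ties; the tie-corrected
#' H statistic is referred to a chi-square distribution with k - 1
#' degrees of freedom.
#'
#' @param x Either a list of per-group numeric vectors, or a numeric
#'   vector paired with group labels `g`.
#' @param g Group labels (ignored when `x` is a list).
#' @return List with `statistic` (H), `df` and `p.value`.
#' @export
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
kruskal_wallis <- function(x, g = NULL) {
  groups <- as_grouped(x, g)
  kt <- stats::kruskal.test(groups)
  H <- unname(kt$statistic)
  p <- unname(kt$p.value)
  if (!is.finite(H)) {
    # all observations tied across every group: no evidence of difference
    H <- 0
    p <- 1
  }
  list(statistic = H, df = unname(kt$parameter), p.value = p)
}

#' Conover-Iman pairwise comparisons after Kruskal-Wallis
#'
#' Rank-based all-pairs comparisons (Conover & Iman 1979): t statistics
#' on rank means with the pooled tie-corrected rank variance and N - k
#' degrees of freedom, two-sided p-values, and optional Bonferroni
#' correction (multiplication by the number of pairs, capped at 1).
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level applied to the adjusted p-values.
#' @param bonferroni Apply the Bonferroni correction (default `TRUE`).
#' @return Data frame with one row per unordered pair: `group1`,
#'   `group2`, `statistic`, `p.value`, `p.adjusted`, `significant`.
#' @export
conover_iman <- function(x, g = NULL, alpha = 0.05, bonferroni = TRUE) {
  groups <- as_grouped(x, g)
  k <- length(groups)
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (N - k < 1L) stop("invalid input: need N > k observations", call. = FALSE)
  r <- rank(pooled)
  gi <- rep(seq_len(k), sizes)
  rbar <- tapply(r, gi, mean)
  # pooled tie-corrected rank variance
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- if (S2 > 0) {
    (sum(sizes * rbar^2) - N * (N + 1)^2 / 4) / S2
  } else 0
  D <- S2 * (N - 1 - H) / (N - k)
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(D * (1 / sizes[i] + 1 / sizes[j]))
    tstat <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p <- 2 * stats::pt(-abs(tstat), df = N - k)
    c(tstat, p)
  })
  p_raw <- pmin(1, res[2, ])
  p_adj <- if (bonferroni) pmin(1, p_raw * n_pairs) else p_raw
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             statistic = res[1, ],
             p.value = p_raw,
             p.adjusted = p_adj,
             significant = p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Two-sample rank-sum (Wilcoxon / Mann-Whitney) test
#'
#' Two-sided rank-sum test with mid-ranks for ties. When the combined
#' sample size is at most `exact_limit` the p-value is computed by exact
#' enumeration of all assignments of the pooled mid-ranks to the two
#' samples (so it is exact even under ties); otherwise a normal
#' approximation with tie-corrected variance is used.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param exact_limit Combined-size threshold for exact enumeration
#'   (default 12).
#' @return List with `statistic` (rank sum of `a`), `p.value` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value  # exact 0.1
rank_sum_test <- function(a, b, exact_limit = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) {
    stop("invalid input: both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  if (N <= exact_limit) {
    sums <- utils::combn(N, na, function(idx) sum(r[idx]))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    p <- if (sigma2 > 0) min(1, 2 * stats::pnorm(-abs(w - mu) / sqrt(sigma2)))
         else 1
    method <- "normal"
  }
  list(statistic = w, p.value = p, method = method)
}

#' Compact letter display from pairwise comparisons
#'
#' Assigns letters to groups by the insert-and-absorb algorithm so that
#' two groups share at least one letter exactly when their pairwise
#' comparison is not significant (the convention of hut-trial summary
#' tables: values not sharing a letter differ significantly). Letters are
#' labelled a, b, c, ... in order of first use over the groups in input
#' order.
#'
#' @param pairwise Data frame with columns `group1`, `group2` and
#'   `significant` covering every unordered pair (e.g. from
#'   [conover_iman()]). A pair listed twice with conflicting flags is an
#'   error.
#' @return Named character vector of letter strings, one per group.
#' @export
#' @examples
#' pw <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
#'                  significant = c(FALSE, TRUE, TRUE))
#' compact_letter_display(pw)
compact_letter_display <- function(pairwise) {
  need <- c("group1", "group2", "significant")
  if (!all(need %in% names(pairwise))) {
    stop("`pairwise` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(c(rbind(pairwise$group1, pairwise$group2)))
  key <- paste(pmin(pairwise$group1, pairwise$group2),
               pmax(pairwise$group1, pairwise$group2), sep = "\r")
  sig <- pairwise$significant
  if (anyDuplicated(key)) {
    agg <- tapply(sig, key, function(v) length(unique(v)))
    if (any(agg > 1)) {
      stop("validation error: pair listed twice with conflicting ",
           "significance flags", call. = FALSE)
    }
    sig <- sig[!duplicated(key)]
    key <- key[!duplicated(key)]
  }
  all_pairs <- utils::combn(groups, 2)
  all_keys <- paste(pmin(all_pairs[1, ], all_pairs[2, ]),
                    pmax(all_pairs[1, ], all_pairs[2, ]), sep = "\r")
  if (!all(all_keys %in% key)) {
    stop("validation error: pairwise results must cover all pairs",
         call. = FALSE)
  }

  # insert-and-absorb: start from one column holding every group; split a
  # column on each significant pair; drop columns contained in another
  cols <- list(groups)
  sig_pairs <- all_pairs[, sig[match(all_keys, key)], drop = FALSE]
  if (ncol(sig_pairs)) {
    for (p in seq_len(ncol(sig_pairs))) {
      gi <- sig_pairs[1, p]; gj <- sig_pairs[2, p]
      new_cols <- list()
      for (col in cols) {
        if (gi %in% col && gj %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, gi)),
                        list(setdiff(col, gj)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[lengths(cols) > 0]
  # letters in first-use order over groups in input order
  first_idx <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first_idx)]
  lab <- make_letter_labels(length(cols))
  out <- vapply(groups, function(g) {
    paste(lab[vapply(cols, function(col) g %in% col, logical(1))],
          collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

make_letter_labels <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, paste0(rep(letters, each = 26), letters))[seq_len(n)]
}

#' Summary table with significance letters
#'
#' Per-group n, mean and SD of per-hut-night values, annotated with the
#' compact letter display from Conover-Iman pairwise comparisons.
#'
#' @inheritParams conover_iman
#' @return Data frame with columns `group`, `n`, `mean`, `sd`, `letters`.
#' @export
letter_summary <- function(x, g = NULL, alpha = 0.05, bonferroni = TRUE) {
  groups <- as_grouped(x, g)
  pw <- conover_iman(groups, alpha = alpha, bonferroni = bonferroni)
  cld <- compact_letter_display(pw)
  data.frame(group = names(groups),
             n = lengths(groups),
             mean = vapply(groups, mean, numeric(1)),
             sd = vapply(groups, stats::sd, numeric(1)),
             letters = unname(cld[names(groups)]),
             stringsAsFactors = FALSE, row.names = NULL)
}
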