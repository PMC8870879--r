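#' Configuration for the hybrid feature selector
#'
#' @param relevance_threshold Relevance rule for step 1. The default `NULL`
#'   keeps a feature when its plug-in mutual information with the target is
#'   significant under the chi-square independence null
#'   (`2 n ln2 * MI ~ chisq((r-1)(c-1))`) at `relevance_alpha` — a
#'   data-adaptive threshold that tracks the estimation-bias floor instead
#'   of a fixed SU cut. A numeric value keeps features with
#'   `SU(feature, target) >= relevance_threshold` (0 keeps everything).
#' @param relevance_alpha Significance level of the chi-square relevance
#'   test (default 0.001).
#' @param p_start,p_step,p_floor Schedule for the redundancy constant p:
#'   starts at `p_start` (default 2.0) and decreases by `p_step` (0.1) down
#'   to `p_floor` (1.0). Larger p removes fewer features.
#' @param msu_stop Near-zero MSU value at which the redundancy rounds stop
#'   early (default 0.05): once the surviving set plus target has MSU at or
#'   below it, the set is considered non-redundant.
#' @param relieff_k Number of nearest hits/misses (default 10).
#' @param relieff_m Number of sampled instances; `NULL` (default) uses all
#'   rows, which gives the most credible weight estimates.
#' @param target_bins Quantile classes for discretizing a continuous target
#'   for ReliefF (default 5).
#' @param prerank_fraction Fraction of features (by SU with target) kept
#'   before ReliefF weight computation. Default 1 (no cut): a marginal-SU
#'   cut is blind to pure interactions, which are exactly what ReliefF is
#'   there to catch; lower it for very wide tables where the
#'   nearest-neighbor scans dominate cost.
#' @param top_k Final fused list length (default 12).
#' @param n_bins Discretization bins for SU/MSU; `NULL` = data-driven default.
#' @return A `"bp_selection_config"` list.
#' @export
selection_config <- function(relevance_threshold = NULL,
                             relevance_alpha = 0.001, p_start = 2.0,
                             p_step = 0.1, p_floor = 1.0, msu_stop = 0.05,
                             relieff_k = 10L, relieff_m = NULL,
                             target_bins = 5L, prerank_fraction = 1,
                             top_k = 12L, n_bins = NULL) {
  if (!is.null(relevance_threshold)) {
    stopifnot(relevance_threshold >= 0, relevance_threshold < 1)
  }
  stopifnot(relevance_alpha > 0, relevance_alpha < 1,
            p_start >= p_floor, p_floor >= 1, msu_stop > 0, msu_stop < 1,
            top_k >= 1)
  structure(list(relevance_threshold = relevance_threshold,
                 relevance_alpha = relevance_alpha, p_start = p_start,
                 p_step = p_step, p_floor = p_floor, msu_stop = msu_stop,
                 relieff_k = as.integer(relieff_k), relieff_m = relieff_m,
                 target_bins = as.integer(target_bins),
                 prerank_fraction = prerank_fraction, top_k = as.integer(top_k),
                 n_bins = n_bins),
            class = "bp_selection_config")
}

table_bins <- function(data, config) {
  if (!is.null(config$n_bins)) config$n_bins else default_bins(nrow(data))
}

discretize_table <- function(data, target, config) {
  nb <- table_bins(data, config)
  feats <- setdiff(names(data), target)
  disc <- lapply(data[feats], discretize, n_bins = nb)
  list(features = disc, target = discretize(data[[target]], n_bins = nb),
       n_bins = nb)
}

#' Relevance step of the fast-correlation filter
#'
#' Computes the symmetric uncertainty of every feature with the target
#' (pairwise MSU equals SU), ranks features by it, and keeps the set S1 of
#' relevant features: either those passing the chi-square independence test
#' on the plug-in MI (default) or those with SU at or above a fixed
#' threshold delta.
#'
#' @param data Data frame of numeric feature columns plus the target column.
#' @param target Name of the target column.
#' @param config A [selection_config()].
#' @return List with `su_ranking` (tibble `feature`, `su`, `mi`, sorted by
#'   SU descending, ties by column order) and `s1` (character vector, SU
#'   order).
#' @export
fc_step1_relevance <- function(data, target, config = selection_config()) {
  stopifnot(target %in% names(data), ncol(data) >= 3)
  dt <- discretize_table(data, target, config)
  n <- nrow(data)
  su <- vapply(dt$features, symmetric_uncertainty, numeric(1), y = dt$target)
  mi <- vapply(dt$features, mutual_information, numeric(1), y = dt$target)
  miv <- unname(mi[names(su)])
  ranking <- tibble::tibble(feature = names(su), su = unname(su), mi = miv) |>
    dplyr::arrange(dplyr::desc(.data$su))
  if (is.null(config$relevance_threshold)) {
    # G-statistic: 2 n ln2 * MI ~ chisq_{(r-1)(c-1)} under independence
    ky <- length(unique(dt$target$labels))
    keep <- vapply(ranking$feature, function(f) {
      kf <- length(unique(dt$features[[f]]$labels))
      df <- max(1L, (kf - 1L) * (ky - 1L))
      crit <- stats::qchisq(1 - config$relevance_alpha, df) / (2 * n * log(2))
      mi[f] >= crit
    }, logical(1))
  } else {
    keep <- ranking$su >= config$relevance_threshold
  }
  s1 <- ranking$feature[keep]
  if (!length(s1)) warning("no feature reaches the relevance threshold; S1 is empty")
  list(su_ranking = ranking, s1 = s1)
}

#' Redundancy-elimination step of the fast-correlation filter
#'
#' Walks the relevant set S1 in descending SU-with-target order; a
#' lower-ranked feature f_j is marked redundant to a kept feature f_i when
#' `SU(f_i, f_j) >= p * SU(f_j, target)`. The constant p starts high (few
#' removals) and is decreased by `p_step` each round down to `p_floor`; after
#' each round the multivariate symmetric uncertainty of the surviving set
#' plus target is computed and the schedule stops early once it falls to the
#' configured near-zero value, indicating a predominant, non-redundant set.
#' Every removal is recorded in an audit log.
#'
#' @inheritParams fc_step1_relevance
#' @param step1 A [fc_step1_relevance()] result (computed if `NULL`).
#' @return List with `s_prime` (surviving features, SU order), `final_p`,
#'   `final_msu`, `audit` (tibble: round p, removed feature, displacing
#'   feature, SU values), and `rounds` (tibble: p, set size, MSU).
#' @export
fc_step2_redundancy <- function(data, target, config = selection_config(),
                                step1 = NULL) {
  if (is.null(step1)) step1 <- fc_step1_relevance(data, target, config)
  s1 <- step1$s1
  if (!length(s1)) {
    return(list(s_prime = character(0), final_p = NA_real_,
                final_msu = NA_real_, audit = tibble::tibble(),
                rounds = tibble::tibble()))
  }
  dt <- discretize_table(data, target, config)
  su_t <- stats::setNames(step1$su_ranking$su, step1$su_ranking$feature)
  pair_su <- local({
    cache <- new.env(parent = emptyenv())
    function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "\r")
      if (!is.null(cache[[key]])) return(cache[[key]])
      v <- symmetric_uncertainty(dt$features[[a]], dt$features[[b]])
      cache[[key]] <- v
      v
    }
  })
  p_sched <- seq(config$p_start, config$p_floor, by = -config$p_step)
  audit <- list(); rounds <- list()
  s_prime <- s1; final_p <- p_sched[1]; final_msu <- NA_real_
  for (p in p_sched) {
    kept <- character(0); removed <- list()
    for (fj in s1) { # s1 is already in descending SU-with-target order
      redundant_to <- NULL
      for (fi in kept) {
        if (pair_su(fi, fj) >= p * su_t[fj]) { redundant_to <- fi; break }
      }
      if (is.null(redundant_to)) {
        kept <- c(kept, fj)
      } else {
        removed[[length(removed) + 1L]] <- tibble::tibble(
          p = p, removed = fj, displaced_by = redundant_to,
          su_pair = pair_su(redundant_to, fj), su_target = unname(su_t[fj]))
      }
    }
    s_prime <- kept; final_p <- p
    audit <- c(audit, removed)
    m <- if (length(kept) >= 1) {
      # the k+1-way joint table must fit the capacity guard: re-discretize
      # at coarser bins when the surviving set is large
      allowed <- max(2L, floor(1e7^(1 / (length(kept) + 1))))
      if (allowed < dt$n_bins) {
        vars <- c(lapply(data[kept], discretize, n_bins = allowed),
                  list(discretize(data[[target]], n_bins = allowed)))
      } else {
        vars <- c(dt$features[kept], list(dt$target))
      }
      msu(vars)
    } else {
      NA_real_
    }
    final_msu <- m
    rounds[[length(rounds) + 1L]] <- tibble::tibble(p = p, size = length(kept), msu = m)
    if (!is.na(m) && m <= config$msu_stop) break
  }
  list(s_prime = s_prime, final_p = final_p, final_msu = final_msu,
       audit = dplyr::bind_rows(audit), rounds = dplyr::bind_rows(rounds))
}

#' ReliefF difference function
#'
#' Contribution of one feature to the distance between two instances:
#' 0/1 match for nominal features; `|v1 - v2| / (max - min)` for numeric
#' features (0 with a warning when the feature has zero range).
#'
#' @param v1,v2 Feature values of the two instances.
#' @param kind `"numeric"` or `"nominal"`.
#' @param range Numeric `c(min, max)` of the feature (numeric kind).
#' @return Difference in \[0, 1\].
#' @export
relieff_diff <- function(v1, v2, kind = c("numeric", "nominal"), range = NULL) {
  kind <- match.arg(kind)
  if (kind == "nominal") return(as.numeric(v1 != v2))
  stopifnot(!is.null(range))
  span <- range[2] - range[1]
  if (span <= 0) { warning("zero feature range"); return(0) }
  abs(v1 - v2) / span
}

#' ReliefF feature weights with MSU pre-ranking
#'
#' The continuous target is discretized into quantile classes so the
#' multiclass weight update with class priors applies. Features are
#' pre-ranked by SU with the target and only the top fraction enters the
#' weight computation (the pre-ranking step cuts the cost of the
#' nearest-neighbor scans). For each sampled instance the k nearest hits
#' (same class) and, per other class, k nearest misses are found under
#' Manhattan distance over min-max-scaled features; each feature's weight is
#' decreased by its mean diff to the hits and increased by the prior-weighted
#' mean diff to the misses, normalized by `m * k`, giving weights in
#' \[-1, 1\].
#'
#' @inheritParams fc_step1_relevance
#' @param seed Seed for the instance sampling (only used when `relieff_m`
#'   is smaller than the number of rows).
#' @return Tibble `feature`, `weight`, sorted by weight descending; attribute
#'   `prerank` holds the SU pre-ranking used.
#' @export
relieff_weights <- function(data, target, config = selection_config(), seed = 1L) {
  stopifnot(target %in% names(data))
  feats <- setdiff(names(data), target)
  dt <- discretize_table(data, target, config)
  su <- vapply(dt$features, symmetric_uncertainty, numeric(1), y = dt$target)
  ord <- names(sort(su, decreasing = TRUE))
  keep <- ord[seq_len(max(2L, ceiling(length(ord) * config$prerank_fraction)))]

  y <- discretize(data[[target]], n_bins = config$target_bins)$labels
  X <- as.matrix(data[keep])
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span <= 0] <- 1
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/") # per-feature [0,1] scaling
  n <- nrow(Xs); p <- ncol(Xs)
  classes <- sort(unique(y))
  prior <- as.numeric(table(factor(y, levels = classes))) / n
  names(prior) <- classes

  m <- if (is.null(config$relieff_m)) n else min(config$relieff_m, n)
  idx <- if (m < n) { set.seed(seed); sample.int(n, m) } else seq_len(n)
  k0 <- config$relieff_k
  W <- numeric(p)
  by_class <- split(seq_len(n), y)
  Xt <- t(Xs) # p x n: per-feature diffs come out as columns
  for (i in idx) {
    di <- abs(Xt - Xs[i, ]) # recycles instance i down each column
    dist <- colSums(di)
    ci <- y[i]
    hits <- setdiff(by_class[[as.character(ci)]], i)
    k_h <- min(k0, length(hits))
    if (k_h > 0) {
      nh <- hits[order(dist[hits])][seq_len(k_h)]
      W <- W - rowSums(di[, nh, drop = FALSE]) / (m * k_h)
    }
    for (cc in setdiff(classes, ci)) {
      miss <- by_class[[as.character(cc)]]
      k_m <- min(k0, length(miss))
      if (k_m == 0) next
      nm <- miss[order(dist[miss])][seq_len(k_m)]
      w_c <- prior[as.character(cc)] / (1 - prior[as.character(ci)])
      W <- W + w_c * rowSums(di[, nm, drop = FALSE]) / (m * k_m)
    }
  }
  out <- tibble::tibble(feature = keep, weight = W) |>
    dplyr::arrange(dplyr::desc(.data$weight))
  attr(out, "prerank") <- tibble::tibble(feature = names(su)[order(-su)],
                                         su = sort(su, decreasing = TRUE))
  out
}

#' Fuse two feature rankings by mean rank
#'
#' Features absent from one ranking get that ranking's worst rank + 1. Ties
#' are broken by the fast-correlation rank, then by column order.
#'
#' @param fc_order Character vector: fast-correlation ranking (best first).
#' @param relieff_order Character vector: ReliefF ranking (best first).
#' @param top_k Number of features to return.
#' @return Tibble `feature`, `fc_rank`, `relieff_rank`, `mean_rank`, best
#'   first, truncated to `top_k`.
#' @export
fuse_rankings <- function(fc_order, relieff_order, top_k = 12L) {
  universe <- union(fc_order, relieff_order)
  fc_rank <- stats::setNames(rep(length(fc_order) + 1L, length(universe)), universe)
  fc_rank[fc_order] <- seq_along(fc_order)
  rf_rank <- stats::setNames(rep(length(relieff_order) + 1L, length(universe)), universe)
  rf_rank[relieff_order] <- seq_along(relieff_order)
  fcv <- unname(fc_rank[universe]); rfv <- unname(rf_rank[universe])
  out <- tibble::tibble(feature = universe, fc_rank = fcv,
                        relieff_rank = rfv, mean_rank = (fcv + rfv) / 2) |>
    dplyr::arrange(.data$mean_rank, .data$fc_rank)
  if (top_k > nrow(out)) {
    warning("top_k exceeds available features; returning all")
    top_k <- nrow(out)
  }
  out[seq_len(top_k), ]
}

#' Pearson-correlation baseline ranking
#'
#' Ranks features by absolute product-moment correlation with the target —
#' the linear baseline the information-theoretic selector is compared
#' against. Constant columns rank last and are flagged.
#'
#' @inheritParams fc_step1_relevance
#' @return Tibble `feature`, `r`, `abs_r`, `flag`, sorted by `abs_r`
#'   descending.
#' @export
pearson_baseline_rank <- function(data, target) {
  stopifnot(target %in% names(data))
  feats <- setdiff(names(data), target)
  y <- data[[target]]
  r <- vapply(feats, function(f) {
    x <- data[[f]]
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  tibble::tibble(feature = feats, r = unname(r),
                 abs_r = abs(unname(r)),
                 flag = ifelse(is.na(r), "constant", "")) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$r)), dplyr::desc(.data$abs_r))
}

#' Run the full hybrid feature selector
#'
#' Relevance filtering (SU threshold), redundancy elimination (p-scheduled
#' pairwise SU test with MSU stopping), ReliefF weighting with MSU
#' pre-ranking, and mean-rank fusion of the two orderings into the final
#' top-k list.
#'
#' @inheritParams fc_step1_relevance
#' @param seed Seed forwarded to [relieff_weights()].
#' @return A `"bp_selection"` list: `su_ranking`, `s1`, `s_prime`, `final_p`,
#'   `final_msu`, `relieff`, `fused`, `audit`, `config`.
#' @export
select_features <- function(data, target, config = selection_config(), seed = 1L) {
  s1 <- fc_step1_relevance(data, target, config)
  s2 <- fc_step2_redundancy(data, target, config, step1 = s1)
  rw <- relieff_weights(data, target, config, seed = seed)
  fused <- fuse_rankings(s2$s_prime, rw$feature,
                         top_k = min(config$top_k,
                                     length(union(s2$s_prime, rw$feature))))
  structure(list(su_ranking = s1$su_ranking, s1 = s1$s1,
                 s_prime = s2$s_prime, final_p = s2$final_p,
                 final_msu = s2$final_msu, relieff = rw, fused = fused,
                 audit = s2$audit, rounds = s2$rounds,
                 config = config, seed = seed, target = target),
            class = "bp_selection")
}

#' @export
print.bp_selection <- function(x, ...) {
  cat("Hybrid MSU feature selection (target:", x$target, ")\n")
  cat("  S1 (relevant):      ", length(x$s1), "features\n")
  cat("  S' (predominant):   ", length(x$s_prime), "features at p =",
      format(x$final_p), ", MSU =", format(x$final_msu, digits = 3), "\n")
  cat("  Fused top-", nrow(x$fused), ": ",
      paste(x$fused$feature, collapse = ", "), "\n", sep = "")
  invisible(x)
}
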