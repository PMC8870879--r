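#' Discretize a numeric variable into categories
#'
#' Entropy-based dependence measures operate on discrete distributions, so
#' continuous physiological features are binned first. The default strategy is
#' equal-frequency (quantile) binning, which is robust to the skewed,
#' heavy-tailed distributions typical of pulse-waveform features; equal-width
#' binning is available for comparison. Bin edges are stored so the same
#' discretization can be re-applied to held-out data.
#'
#' @param x Numeric vector (or an integer/factor already treated as labels).
#' @param n_bins Number of categories (>= 2). Default
#'   `default_bins(length(x))` = `max(2, floor(sqrt(n)/2))` capped at 10.
#' @param strategy `"equal-frequency"` (default) or `"equal-width"`.
#' @param edges Optional numeric vector of interior bin edges from a previous
#'   call; when supplied, `n_bins`/`strategy` are ignored and the stored
#'   edges are re-applied (idempotent on the training data).
#'
#' @return An object of class `"bp_discretized"`: a list with integer
#'   `labels` in `1..n_bins`, `n_bins`, `strategy`, and `edges`.
#' @export
#' @examples
#' d <- discretize(rnorm(100), n_bins = 4)
#' table(d$labels)
discretize <- function(x, n_bins = default_bins(length(x)),
                       strategy = c("equal-frequency", "equal-width"),
                       edges = NULL) {
  if (is.factor(x)) x <- as.integer(x)
  stopifnot(is.numeric(x), length(x) > 0L)
  strategy <- match.arg(strategy)
  if (!is.null(edges)) {
    labels <- findInterval(x, vec = edges, left.open = TRUE) + 1L
    return(structure(list(labels = labels, n_bins = length(edges) + 1L,
                          strategy = strategy, edges = edges),
                     class = "bp_discretized"))
  }
  if (n_bins < 2L) stop("`n_bins` must be >= 2")
  ux <- unique(x)
  if (length(ux) == 1L) {
    warning("constant input: single-category variable")
    return(structure(list(labels = rep(1L, length(x)), n_bins = 1L,
                          strategy = strategy, edges = numeric(0)),
                     class = "bp_discretized"))
  }
  n_bins <- min(n_bins, length(ux))
  if (strategy == "equal-frequency") {
    # ranks break ties by original order, guaranteeing near-equal bin counts
    r <- rank(x, ties.method = "first")
    labels <- as.integer(ceiling(r * n_bins / length(x)))
    edges <- stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                             names = FALSE, type = 1)
  } else {
    edges <- seq(min(x), max(x), length.out = n_bins + 1L)[-c(1L, n_bins + 1L)]
    labels <- findInterval(x, vec = edges, left.open = TRUE) + 1L
  }
  structure(list(labels = labels, n_bins = n_bins, strategy = strategy,
                 edges = edges),
            class = "bp_discretized")
}

#' @rdname discretize
#' @param n Sample size.
#' @export
default_bins <- function(n) min(10L, max(2L, as.integer(floor(sqrt(n) / 2))))

as_labels <- function(x) {
  if (inherits(x, "bp_discretized")) return(x$labels)
  if (is.factor(x)) return(as.integer(x))
  if (is.numeric(x) && all(x == round(x))) return(as.integer(x))
  stop("expected a bp_discretized object or integer labels; ",
       "discretize() continuous data first")
}

#' Shannon entropy of a discrete variable (bits)
#'
#' Plug-in estimate \eqn{H(X) = -\sum_i \hat p_i \log_2 \hat p_i} with the
#' convention \eqn{0 \log 0 = 0}.
#'
#' @param x A [discretize()] result or an integer label vector.
#' @return Entropy in bits (non-negative scalar).
#' @export
entropy <- function(x) {
  p <- tabulate_probs(as_labels(x))
  -sum(p * log2(p))
}

tabulate_probs <- function(labels) {
  cnt <- table(labels)
  p <- as.numeric(cnt) / length(labels)
  p[p > 0]
}

joint_labels <- function(...) {
  vars <- list(...)
  lab <- lapply(vars, as_labels)
  n <- unique(lengths(lab))
  if (length(n) != 1L) stop("variables must have equal length")
  # collapse the tuple to a single label via an interaction key
  interaction(as.data.frame(lab), drop = TRUE, lex.order = TRUE)
}

#' Conditional entropy H(X | Y) in bits
#'
#' Computed from the joint frequency table as `H(X,Y) - H(Y)`, which equals
#' the prior-weighted sum of per-stratum entropies. Always >= 0.
#'
#' @param x,y [discretize()] results or integer label vectors of equal length.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(x, y) {
  hxy <- entropy(as.integer(joint_labels(x, y)))
  max(0, hxy - entropy(y))
}

#' Mutual information MI(X; Y) in bits
#'
#' `MI = H(X) - H(X|Y)`; symmetric in its arguments and non-negative up to
#' floating error.
#'
#' @inheritParams conditional_entropy
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  mi <- entropy(x) - conditional_entropy(x, y)
  max(0, mi)
}

#' Symmetric uncertainty SU(X, Y)
#'
#' Normalized mutual information `SU = 2 MI / (H(X) + H(Y))`, a dependence
#' measure in \[0, 1\]: 0 for independent variables, 1 for a deterministic
#' one-to-one relation. The normalization corrects the bias of raw information
#' gain towards high-cardinality variables.
#'
#' @inheritParams conditional_entropy
#' @return SU in \[0, 1\]; `NA` with a warning if both variables are constant.
#' @export
symmetric_uncertainty <- function(x, y) {
  hx <- entropy(x); hy <- entropy(y)
  if (hx + hy <= 0) {
    warning("both variables constant: SU undefined")
    return(NA_real_)
  }
  su <- 2 * mutual_information(x, y) / (hx + hy)
  min(1, max(0, su))
}

#' Joint entropy of several discrete variables (bits)
#'
#' Plug-in entropy of the n-way contingency table. A capacity guard rejects
#' joint tables above 1e7 potential cells; callers should reduce bin counts
#' instead (the pipeline only evaluates multivariate entropies on the small
#' predominant feature set).
#'
#' @param vars List of [discretize()] results / integer label vectors.
#' @return Joint entropy in bits.
#' @export
joint_entropy_multi <- function(vars) {
  stopifnot(is.list(vars), length(vars) >= 1L)
  lab <- lapply(vars, as_labels)
  cells <- prod(vapply(lab, function(l) length(unique(l)), numeric(1)))
  if (cells > 1e7) {
    stop("joint table capacity guard exceeded (", format(cells, digits = 3),
         " potential cells > 1e7); reduce the number of bins or variables")
  }
  entropy(as.integer(do.call(joint_labels, lab)))
}

#' Total correlation (multi-information) in bits
#'
#' `C(X_1..X_n) = sum_i H(X_i) - H(X_1..X_n)`; zero iff the variables are
#' jointly independent (in the population), and for n = 2 identical to mutual
#' information.
#'
#' @inheritParams joint_entropy_multi
#' @return Total correlation in bits (>= 0 up to floating error).
#' @export
total_correlation <- function(vars) {
  stopifnot(length(vars) >= 2L)
  max(0, sum(vapply(vars, entropy, numeric(1))) - joint_entropy_multi(vars))
}

#' Multivariate symmetric uncertainty (MSU)
#'
#' Extends symmetric uncertainty to n variables:
#' \deqn{MSU = \frac{n}{n-1}\left(1 - \frac{H(X_{1:n})}{\sum_i H(X_i)}\right)}
#' The `n/(n-1)` normalization multiplier maps the attainable range onto
#' \[0, 1\]; for n = 2 MSU reduces exactly to SU.
#'
#' @inheritParams joint_entropy_multi
#' @return MSU in \[0, 1\]; `NA` with a warning when all variables are
#'   constant.
#' @export
msu <- function(vars) {
  stopifnot(length(vars) >= 2L)
  n <- length(vars)
  hsum <- sum(vapply(vars, entropy, numeric(1)))
  if (hsum <= 0) {
    warning("all variables constant: MSU undefined")
    return(NA_real_)
  }
  val <- (n / (n - 1)) * (1 - joint_entropy_multi(vars) / hsum)
  min(1, max(0, val))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] used for the linear-baseline feature
#' ranking; returns `NA` with a warning for constant input.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
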