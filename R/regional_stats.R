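#' Regional summaries of uptake rates
#'
#' For each water mass: per-substrate mean and SD of the absolute rates,
#' the mean/range/n of the total uptake per experiment set (the sum of the
#' six substrate rates at one station/depth; sets missing any substrate
#' after quality-control exclusion are dropped from totals, not imputed),
#' and each substrate's fraction of the total (substrate mean / total
#' mean, which sums to 1 within a region).
#'
#' @param rates output of [compute_uptake_rates()].
#' @param labels data frame with `station_id` and `water_mass` (one row per
#'   station, e.g. distinct rows of [classify_hydro()] output).
#' @return list with `substrates` (region x substrate long table) and
#'   `totals` (one row per region).
#' @export
regional_summary <- function(rates, labels) {
  lab <- unique(labels[, c("station_id", "water_mass")])
  if (anyDuplicated(lab$station_id)) {
    stop("labels must give a single water mass per station")
  }
  r <- merge(rates, lab, by = "station_id")
  if (nrow(r) < nrow(rates)) warning("some rate rows had no water-mass label")
  r <- r[!is_excluded(r$flags) & !is.na(r$rate_umolN_L_h), ]
  if (!nrow(r)) stop("no valid experiments after exclusions")
  sub_rows <- list(); tot_rows <- list()
  for (reg in unique(r$water_mass)) {
    rr <- r[r$water_mass == reg, ]
    # totals over complete experiment sets only
    key <- interaction(rr$station_id, rr$depth_id, drop = TRUE)
    totals <- vapply(split(rr, key), function(s) {
      if (all(SUBSTRATES %in% s$substrate)) sum(s$rate_umolN_L_h) else NA_real_
    }, numeric(1))
    totals <- totals[!is.na(totals)]
    if (!length(totals)) {
      warning("region ", reg, " has no complete experiment sets; omitted")
      next
    }
    sub_mean <- vapply(SUBSTRATES, function(s)
      mean(rr$rate_umolN_L_h[rr$substrate == s]), numeric(1))
    sub_sd <- vapply(SUBSTRATES, function(s) {
      x <- rr$rate_umolN_L_h[rr$substrate == s]
      if (length(x) > 1) stats::sd(x) else 0
    }, numeric(1))
    spec_mean <- vapply(SUBSTRATES, function(s)
      mean(rr$specific_rate_h[rr$substrate == s]), numeric(1))
    sub_rows[[reg]] <- data.frame(
      region = reg, substrate = SUBSTRATES,
      mean_rate_umolN_L_h = unname(sub_mean), sd_rate = unname(sub_sd),
      mean_specific_rate_h = unname(spec_mean),
      fraction_of_total = unname(sub_mean / sum(sub_mean)),
      n = vapply(SUBSTRATES, function(s) sum(rr$substrate == s), integer(1)),
      stringsAsFactors = FALSE)
    tot_rows[[reg]] <- data.frame(
      region = reg, mean_total_umolN_L_h = mean(totals),
      min_total = min(totals), max_total = max(totals),
      n_sets = length(totals), stringsAsFactors = FALSE)
  }
  list(substrates = do.call(rbind, c(sub_rows, list(make.row.names = FALSE))),
       totals = do.call(rbind, c(tot_rows, list(make.row.names = FALSE))))
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties. The p-value is exact (full
#' enumeration of rank assignments) when n_a + n_b <= `exact_limit` and
#' there are no ties; otherwise a normal approximation with tie and
#' continuity corrections is used. Two-sided exact p doubles the smaller
#' tail (capped at 1).
#'
#' @param a,b numeric samples (each non-empty).
#' @param exact_limit maximum combined size for the exact enumeration.
#' @return list with `U` (statistic for sample `a`), `p`, and `method`
#'   ("exact" or "normal").
#' @export
mann_whitney_u <- function(a, b, exact_limit = 12L) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && N <= exact_limit) {
    # enumerate every assignment of n1 ranks out of N
    combos <- utils::combn(N, n1)
    Us <- colSums(combos) - n1 * (n1 + 1) / 2
    p_lo <- mean(Us <= U)
    p_hi <- mean(Us >= U)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U, p = p, method = "exact"))
  }
  mU <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  varU <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (varU <= 0 || U == mU) return(list(U = U, p = 1, method = "normal"))
  z <- (abs(U - mU) - 0.5) / sqrt(varU)
  z <- max(z, 0)
  list(U = U, p = 2 * stats::pnorm(-z), method = "normal")
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Pearson r for every pair of columns, computed on pairwise-complete rows;
#' pairs with fewer than `min_pairs` complete rows are reported missing.
#'
#' @param x data frame or matrix of numeric columns.
#' @param min_pairs minimum complete pairs required (default 3).
#' @return symmetric correlation matrix with `NA` for unsupported pairs.
#' @export
correlation_matrix <- function(x, min_pairs = 3L) {
  m <- as.matrix(as.data.frame(x))
  storage.mode(m) <- "double"
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  ok <- !is.na(m)
  npairs <- crossprod(ok)
  r[npairs < min_pairs] <- NA_real_
  r
}

#' Redundancy analysis of uptake rates on environment and community
#'
#' Y is centered; X is centered and standardized to unit variance. The
#' fitted values Yhat = X (X'X)^-1 X'Y are eigen-decomposed via
#' Yhat'Yhat/(n-1); axis proportions are eigenvalues over their sum, site
#' scores are the projections of Yhat on the eigenvectors, and response
#' loadings are the correlations of the (centered) response columns with
#' the site scores. Rows with any missing value in Y or X are removed
#' listwise first. Axis signs are fixed so that the loading of
#' `sign_column` on each axis is non-negative.
#'
#' @param Y numeric matrix/data frame of responses (uptake rates).
#' @param X numeric matrix/data frame of explanatory variables.
#' @param sign_column response column (name or index) whose loading fixes
#'   the axis sign; defaults to the first column.
#' @param rank_tol relative eigenvalue threshold below which axes are
#'   dropped.
#' @return list of class `rda_result`: `eigenvalues`, `proportion`,
#'   `loadings` (responses x axes), `site_scores`, `n_used`,
#'   `constrained_variance`, `total_variance`.
#' @export
uptake_rda <- function(Y, X, sign_column = 1L, rank_tol = 1e-10) {
  Y <- as.matrix(as.data.frame(Y)); X <- as.matrix(as.data.frame(X))
  storage.mode(Y) <- "double"; storage.mode(X) <- "double"
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of rows")
  keep <- stats::complete.cases(Y) & stats::complete.cases(X)
  Y <- Y[keep, , drop = FALSE]; X <- X[keep, , drop = FALSE]
  n <- nrow(Y)
  if (n <= ncol(X)) stop("need more complete rows than explanatory columns")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X, center = TRUE, scale = TRUE)
  if (any(!is.finite(Xs))) stop("constant explanatory column; drop it first")
  XtX <- crossprod(Xs)
  qrx <- qr(XtX)
  if (qrx$rank < ncol(Xs)) {
    stop("X'X is singular: drop collinear explanatory columns and refit")
  }
  B <- solve(XtX, crossprod(Xs, Yc))
  Yhat <- Xs %*% B
  C <- crossprod(Yhat) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  pos <- eig$values > rank_tol * max(eig$values, 0)
  ev <- eig$values[pos]
  V <- eig$vectors[, pos, drop = FALSE]
  scores <- Yhat %*% V
  # loadings: correlation of each response with each axis's site scores
  loadings <- suppressWarnings(stats::cor(Yc, scores))
  sc <- if (is.character(sign_column)) match(sign_column, colnames(Y)) else sign_column
  if (is.na(sc)) stop("sign_column not found among response columns")
  flip <- ifelse(loadings[sc, ] < 0, -1, 1)
  scores <- sweep(scores, 2L, flip, `*`)
  loadings <- sweep(loadings, 2L, flip, `*`)
  colnames(scores) <- colnames(loadings) <- paste0("RDA", seq_along(ev))
  structure(list(eigenvalues = ev, proportion = ev / sum(ev),
                 loadings = loadings, site_scores = scores, n_used = n,
                 constrained_variance = sum(ev),
                 total_variance = sum(diag(crossprod(Yc) / (n - 1)))),
            class = "rda_result")
}
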