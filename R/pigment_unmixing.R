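#' Phytoplankton groups resolved by the pigment decomposition
#' @export
PIGMENT_GROUPS <- c("Diat", "Dino", "Hapt8", "Hapt6", "Chlo", "Cryp",
                    "Proc", "Syne", "Pras")

#' Diagnostic pigments used by the decomposition
#'
#' Thirteen diagnostic pigments; chlorophyll a and divinyl-chlorophyll a are
#' carried separately (`ChlA`, `DVChlA`) and sum to total chlorophyll a.
#' @export
DIAGNOSTIC_PIGMENTS <- c("Fuco", "Perid", "But19", "Hex19", "Allo", "Zea",
                         "ChlB", "PrasX", "Viol", "Neo", "Lut", "DVChlB",
                         "ChlC3")

#' The five groups whose chlorophyll sums to the pico-eukaryote aggregate
#' @export
PICOEUK_GROUPS <- c("Hapt8", "Hapt6", "Chlo", "Pras", "Cryp")

#' Default group x pigment ratio matrix
#'
#' Pigment : total-chlorophyll-a ratios for nine phytoplankton groups over
#' the thirteen diagnostic pigments, plus a chlorophyll-a column fixed at 1
#' for every group. Values are illustrative literature-style ratios (the
#' zero pattern encodes which pigments each group may contain); they are
#' meant as a starting matrix for [optimize_ratio_matrix()], not as a fitted
#' product, and can be replaced via the `ratio_matrix` arguments throughout.
#'
#' @return 9 x 14 numeric matrix, rows [PIGMENT_GROUPS], columns
#'   [DIAGNOSTIC_PIGMENTS] then `"ChlA"`.
#' @export
default_ratio_matrix <- function() {
  m <- matrix(0, nrow = length(PIGMENT_GROUPS),
              ncol = length(DIAGNOSTIC_PIGMENTS) + 1L,
              dimnames = list(PIGMENT_GROUPS, c(DIAGNOSTIC_PIGMENTS, "ChlA")))
  m["Diat",  c("Fuco", "ChlC3")] <- c(0.75, 0.08)
  m["Dino",  "Perid"] <- 0.60
  m["Hapt8", c("Hex19", "But19", "ChlC3")] <- c(0.90, 0.10, 0.20)
  m["Hapt6", c("Hex19", "But19", "ChlC3")] <- c(0.45, 0.50, 0.10)
  m["Chlo",  c("ChlB", "Lut", "Viol", "Neo", "Zea")] <- c(0.30, 0.20, 0.06, 0.05, 0.06)
  m["Cryp",  "Allo"] <- 0.35
  m["Proc",  c("DVChlB", "Zea")] <- c(0.35, 0.35)
  m["Syne",  "Zea"] <- 0.45
  m["Pras",  c("PrasX", "ChlB", "Neo", "Viol")] <- c(0.25, 0.50, 0.10, 0.05)
  m[, "ChlA"] <- 1
  m
}

# Expand a group x (13 pigments + ChlA) ratio matrix into the design matrix
# over the 15 measured channels (13 pigments + ChlA + DVChlA): every group's
# chlorophyll a sits in the ChlA channel except Prochlorococcus, whose
# chlorophyll is entirely divinyl and sits in DVChlA.
expand_ratio_matrix <- function(ratios) {
  validate_ratio_matrix(ratios)
  A <- cbind(ratios[, DIAGNOSTIC_PIGMENTS, drop = FALSE],
             ChlA = ratios[, "ChlA"], DVChlA = 0)
  A["Proc", "DVChlA"] <- A["Proc", "ChlA"]
  A["Proc", "ChlA"] <- 0
  A
}

validate_ratio_matrix <- function(ratios) {
  if (!is.matrix(ratios) ||
      !identical(rownames(ratios), PIGMENT_GROUPS) ||
      !identical(colnames(ratios), c(DIAGNOSTIC_PIGMENTS, "ChlA"))) {
    stop("ratio matrix must have rows ", toString(PIGMENT_GROUPS),
         " and columns ", toString(c(DIAGNOSTIC_PIGMENTS, "ChlA")))
  }
  if (any(ratios < 0)) stop("ratio matrix entries must be non-negative")
  if (any(ratios[, "ChlA"] != 1)) stop("ChlA column must be fixed at 1")
  invisible(TRUE)
}

#' Measured pigment channel names (13 diagnostic + ChlA + DVChlA)
#' @export
PIGMENT_CHANNELS <- c(DIAGNOSTIC_PIGMENTS, "ChlA", "DVChlA")

#' Unmix one pigment profile into group contributions
#'
#' Solves min || p - t(c) A ||_2 subject to c >= 0, where A is the expanded
#' ratio matrix (divinyl chlorophyll a assignable only to Prochlorococcus).
#' Contributions are in chlorophyll-a units (ug L^-1); fractions are
#' normalized over the fitted contributions.
#'
#' @param pigments named numeric vector over [PIGMENT_CHANNELS] (ug L^-1).
#' @param ratios group x pigment ratio matrix, see [default_ratio_matrix()].
#' @return list with `contributions` (named, ug TChl-a L^-1), `fractions`
#'   (sum to 1), `residual_norm`, and `tchla` (fitted total).
#' @export
unmix_sample <- function(pigments, ratios = default_ratio_matrix()) {
  A <- expand_ratio_matrix(ratios)
  if (!all(PIGMENT_CHANNELS %in% names(pigments))) {
    stop("pigment vector must be named over: ", toString(PIGMENT_CHANNELS))
  }
  p <- as.numeric(pigments[PIGMENT_CHANNELS])
  if (any(p < 0)) stop("pigment concentrations must be non-negative")
  if (all(p == 0)) stop("all-zero pigment vector cannot be unmixed")
  if (qr(A)$rank < nrow(A)) {
    warning("rank-deficient ratio matrix; solution is not unique")
  }
  fit <- pracma::lsqnonneg(t(A), p)
  c_hat <- fit$x
  names(c_hat) <- rownames(A)
  total <- sum(c_hat)
  if (total <= 0) stop("unmixing produced no positive contribution")
  list(contributions = c_hat,
       fractions = c_hat / total,
       residual_norm = sqrt(sum((p - as.numeric(t(A) %*% c_hat))^2)),
       tchla = total)
}

#' Unmix a matrix of pigment profiles
#'
#' @param pigment_table data frame with `station_id`, `depth_id` and the
#'   [PIGMENT_CHANNELS] columns, or a numeric matrix with channel columns.
#' @param ratios ratio matrix.
#' @return data frame with per-sample group fractions (columns named by
#'   group), contributions (`chl_<group>`), `tchla_fit`, `residual_norm`,
#'   and `picoeuk` / `chl_picoeuk` aggregates.
#' @export
unmix_pigments <- function(pigment_table, ratios = default_ratio_matrix()) {
  pm <- as.data.frame(pigment_table)
  missing_cols <- setdiff(PIGMENT_CHANNELS, names(pm))
  if (length(missing_cols)) {
    stop("pigment table is missing channel(s): ", toString(missing_cols))
  }
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    u <- unmix_sample(unlist(pm[i, PIGMENT_CHANNELS]), ratios)
    frac <- as.list(u$fractions)
    chl <- as.list(u$contributions)
    names(chl) <- paste0("chl_", names(chl))
    out <- c(frac, chl,
             list(tchla_fit = u$tchla, residual_norm = u$residual_norm))
    out$picoeuk <- aggregate_picoeukaryotes(u$fractions)
    out$chl_picoeuk <- aggregate_picoeukaryotes(u$contributions)
    as.data.frame(out)
  })
  res <- do.call(rbind, rows)
  keep <- intersect(c("station_id", "depth_id", "sample_id"), names(pm))
  if (length(keep)) res <- cbind(pm[, keep, drop = FALSE], res)
  rownames(res) <- NULL
  res
}

#' Sum the pico-eukaryote groups
#'
#' Pico-eukaryote chlorophyll (or fraction) is the sum over haptophytes
#' (Type 8 and Type 6), chlorophytes, prasinophytes and cryptophytes.
#'
#' @param composition named numeric vector over all nine groups
#'   (fractions or chlorophyll contributions).
#' @return scalar sum over the five pico-eukaryote groups.
#' @export
aggregate_picoeukaryotes <- function(composition) {
  missing_groups <- setdiff(PICOEUK_GROUPS, names(composition))
  if (length(missing_groups)) {
    stop("composition is missing group(s): ", toString(missing_groups))
  }
  sum(composition[PICOEUK_GROUPS])
}

# RMS pigment residual of the NNLS fit over all samples. The unconstrained
# least-squares coefficients are computed for every sample in one batch;
# where they are already non-negative they coincide with the NNLS solution
# (interior KKT point), and only the remaining samples fall back to the
# active-set solver.
rms_residual <- function(P, ratios) {
  A <- expand_ratio_matrix(ratios)          # groups x channels
  G <- solve(A %*% t(A), A)                 # (A A')^-1 A, groups x channels
  C_ls <- P %*% t(G)                        # samples x groups
  fitted <- C_ls %*% A
  res2 <- rowSums((P - fitted)^2)
  binding <- which(apply(C_ls, 1L, min) < 0)
  for (i in binding) {
    fit <- pracma::lsqnonneg(t(A), as.numeric(P[i, ]))
    res2[i] <- sum((as.numeric(P[i, ]) - as.numeric(t(A) %*% fit$x))^2)
  }
  sqrt(mean(res2) / ncol(P))
}

#' Optimize the ratio matrix against a pigment data set
#'
#' CHEMTAX-style outer loop implemented as a cyclic coordinate descent:
#' sweeps visit every non-fixed, non-zero ratio entry in a seeded random
#' order; at each visit the entry is tried on a candidate grid spanning
#' +/- `bounds` (fractional) of its initial value, the non-negative
#' least-squares unmixing is re-solved for all samples, and the candidate
#' is kept only if the root-mean-square pigment residual strictly
#' decreases. The chlorophyll-a column and structural zeros are never
#' modified; the objective is monotone non-increasing by construction.
#' Deterministic for a fixed seed (which only shuffles the sweep order).
#'
#' @param pigment_table as in [unmix_pigments()] (only the channel columns
#'   are used).
#' @param ratios initial ratio matrix.
#' @param bounds maximum fractional deviation of any entry from its initial
#'   value, in (0, 1]; `bounds = 0` returns the input unchanged.
#' @param max_iter maximum number of entry visits in total.
#' @param tol stop when a full sweep improves the RMS residual by less than
#'   this relative amount.
#' @param n_candidates grid points per entry visit.
#' @param seed integer seed for the sweep order.
#' @return list with `ratios` (optimized matrix), `rms` (final RMS
#'   residual), `rms_path` (RMS after each accepted step, starting at the
#'   initial value), `n_accepted`, `n_iter` (entry visits), and
#'   `converged`.
#' @export
optimize_ratio_matrix <- function(pigment_table, ratios = default_ratio_matrix(),
                                  bounds = 0.5, max_iter = 500, tol = 1e-6,
                                  n_candidates = 5L, seed = 1L) {
  validate_ratio_matrix(ratios)
  if (bounds < 0 || bounds > 1) stop("bounds must lie in [0, 1]")
  pm <- as.data.frame(pigment_table)
  P <- as.matrix(pm[, PIGMENT_CHANNELS, drop = FALSE])
  free <- which(ratios > 0 & col(ratios) != ncol(ratios), arr.ind = TRUE)
  init <- ratios
  rms0 <- rms_residual(P, ratios)
  if (bounds == 0 || nrow(free) == 0L) {
    return(list(ratios = ratios, rms = rms0, rms_path = rms0,
                n_accepted = 0L, n_iter = 0L, converged = TRUE,
                note = if (nrow(free) == 0L) "no free entries to optimize" else "zero bounds"))
  }
  current <- ratios
  rms_cur <- rms0
  rms_path <- rms0
  n_acc <- 0L
  visits <- 0L
  converged <- FALSE
  local_seed(seed, {
    repeat {
      sweep_start <- rms_cur
      for (j in sample.int(nrow(free))) {
        if (visits >= max_iter) break
        visits <- visits + 1L
        k <- free[j, , drop = FALSE]
        lo <- init[k] * (1 - bounds)
        hi <- init[k] * (1 + bounds)
        eval_at <- function(v) {
          trial <- current
          trial[k] <- v
          rms_residual(P, trial)
        }
        # coarse grid guards against multiple valleys, then a 1-D line
        # search refines within the bracket around the best coarse point
        grid <- seq(lo, hi, length.out = n_candidates)
        grid_rms <- vapply(grid, eval_at, numeric(1))
        g <- which.min(grid_rms)
        bracket <- c(grid[max(1L, g - 1L)], grid[min(length(grid), g + 1L)])
        ref <- stats::optimize(eval_at, bracket,
                               tol = (hi - lo) / (20 * n_candidates))
        cand_vals <- c(grid, ref$minimum)
        cand_rms <- c(grid_rms, ref$objective)
        best <- which.min(cand_rms)
        if (cand_rms[best] < rms_cur) {
          current[k] <- cand_vals[best]
          rms_cur <- cand_rms[best]
          n_acc <- n_acc + 1L
          rms_path <- c(rms_path, rms_cur)
        }
      }
      if (visits >= max_iter) break
      rel <- (sweep_start - rms_cur) / max(sweep_start, .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
  })
  list(ratios = current, rms = rms_cur, rms_path = rms_path,
       n_accepted = n_acc, n_iter = visits, converged = converged)
}
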