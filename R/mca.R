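#' Build the indicator matrix of a coded table
#'
#' One binary column per observed modality, named `variable=label`, in
#' deterministic order (variable order of the coded table, then rule label
#' order, observed labels only). Modalities observed zero times are absent
#' with a warning. Every row sums to the number of active variables Q.
#'
#' @param coded A `clbp_coded` table (or plain data frame of modality
#'   labels with subject rownames).
#' @return A list of class `clbp_indicator`: `Z` (n x J binary matrix),
#'   `Q`, `J`, `variables` (named list variable -> its column names).
#' @export
build_indicator <- function(coded) {
  if (anyNA(coded)) {
    stop("build_indicator(): coded table has absent cells; ",
         "discard incomplete subjects upstream")
  }
  scheme <- attr(coded, "scheme")
  cols <- list()
  varcols <- list()
  for (v in names(coded)) {
    lv <- if (!is.null(scheme) && v %in% names(scheme$rules)) {
      scheme$rules[[v]]$labels
    } else if (v == "npf") c("absent", "present") else sort(unique(coded[[v]]))
    seen <- lv %in% coded[[v]]
    if (any(!seen)) {
      warning("build_indicator(): modality never observed, dropped: ",
              paste(paste0(v, "=", lv[!seen]), collapse = ", "))
      lv <- lv[seen]
    }
    m <- sapply(lv, function(l) as.integer(coded[[v]] == l))
    m <- matrix(m, ncol = length(lv),
                dimnames = list(rownames(coded), paste0(v, "=", lv)))
    cols[[v]] <- m
    varcols[[v]] <- colnames(m)
  }
  Z <- do.call(cbind, cols)
  structure(list(Z = Z, Q = length(coded), J = ncol(Z),
                 variables = varcols),
            class = "clbp_indicator")
}

#' Multiple Correspondence Analysis of an indicator matrix
#'
#' Correspondence analysis of the subjects-by-modalities indicator matrix:
#' with `P = Z / (n Q)`, row masses `r`, column masses `c`, the SVD of the
#' standardized residuals `S = Dr^(-1/2) (P - r c') Dc^(-1/2)` gives
#' singular values whose squares are the principal inertias (eigenvalues)
#' `lambda_k`; modality principal coordinates are
#' `Dc^(-1/2) V diag(sqrt(lambda))`, subject principal coordinates
#' `Dr^(-1/2) U diag(sqrt(lambda))`, and the contribution of modality j to
#' axis k is `c_j g_jk^2 / lambda_k`. The trivial (constant) axis is
#' removed by the centring; numerically null axes are dropped, so
#' rank-deficient inputs simply report fewer axes. Raw and
#' Benzecri-adjusted inertia percentages are both reported.
#'
#' Axes are oriented deterministically: each axis is flipped, if needed,
#' so that `orient_modality` (by default the modality with the largest
#' total contribution) has a non-negative coordinate on it; the pipeline
#' passes the anchor modality (highest pain-interference tercile) so that
#' the worst-state pole of F1 is always positive.
#'
#' @param indicator A `clbp_indicator` from [build_indicator()] (or a
#'   plain binary matrix plus `Q`).
#' @param Q Number of active variables (taken from the indicator object if
#'   absent).
#' @param orient_modality Column name used to fix axis signs, or `NULL`
#'   for the default.
#' @return A list of class `clbp_mca`: `eigenvalues`, `raw_inertia_pct`,
#'   `adjusted_inertia_pct`, `modality_coords`, `modality_contrib_pct`,
#'   `subject_coords`, `modality_mass`, `Q`, `J`, `n`.
#' @export
run_mca <- function(indicator, Q = NULL, orient_modality = NULL) {
  if (inherits(indicator, "clbp_indicator")) {
    Z <- indicator$Z
    Q <- indicator$Q
  } else {
    Z <- as.matrix(indicator)
    if (is.null(Q)) stop("run_mca(): Q is required for a plain matrix")
  }
  if (any(colSums(Z) == 0)) stop("run_mca(): empty modality columns")
  n <- nrow(Z)
  J <- ncol(Z)
  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- (P - outer(r, cm)) / outer(sqrt(r), sqrt(cm))
  sv <- svd(S)
  lam <- sv$d^2
  keep <- which(lam > 1e-12)
  lam <- lam[keep]
  K <- length(keep)
  G <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cm), "/") %*%
    diag(sqrt(lam), K)
  Fc <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/") %*%
    diag(sqrt(lam), K)
  rownames(G) <- colnames(Z)
  rownames(Fc) <- rownames(Z)
  contrib <- sweep(G^2 * cm, 2, lam, "/") * 100
  # deterministic axis orientation
  om <- orient_modality
  if (is.null(om)) om <- colnames(Z)[which.max(rowSums(contrib))]
  if (om %in% rownames(G)) {
    flip <- ifelse(G[om, ] < 0, -1, 1)
    G <- sweep(G, 2, flip, "*")
    Fc <- sweep(Fc, 2, flip, "*")
  }
  colnames(G) <- colnames(Fc) <- colnames(contrib) <- paste0("F", seq_len(K))
  structure(list(
    eigenvalues = lam,
    raw_inertia_pct = 100 * lam / sum(lam),
    adjusted_inertia_pct = benzecri_adjusted_rates(lam, Q),
    modality_coords = G,
    modality_contrib_pct = contrib,
    subject_coords = Fc,
    modality_mass = cm,
    Q = Q, J = J, n = n
  ), class = "clbp_mca")
}

#' Benzecri-adjusted inertia percentages
#'
#' Indicator-matrix MCA eigenvalues below `1/Q` reflect coding artefacts;
#' the Benzecri adjustment rescales those above `1/Q` as
#' `lambda' = (Q / (Q - 1))^2 (lambda - 1/Q)^2` and reports percentages of
#' the adjusted total, with 0% for axes at or below `1/Q`.
#'
#' @param eigenvalues Numeric vector of eigenvalues in `[0, 1]`.
#' @param Q Number of active variables, at least 2.
#' @return Percentages, one per input eigenvalue.
#' @export
benzecri_adjusted_rates <- function(eigenvalues, Q) {
  if (length(Q) != 1 || Q < 2) stop("benzecri_adjusted_rates(): Q must be >= 2")
  if (any(eigenvalues < -1e-12 | eigenvalues > 1 + 1e-12)) {
    stop("benzecri_adjusted_rates(): eigenvalues must lie in [0, 1]")
  }
  adj <- ifelse(eigenvalues > 1 / Q,
                (Q / (Q - 1))^2 * (eigenvalues - 1 / Q)^2, 0)
  tot <- sum(adj)
  if (tot == 0) {
    warning("benzecri_adjusted_rates(): no eigenvalue exceeds 1/Q; ",
            "all adjusted rates are zero")
    return(rep(0, length(adj)))
  }
  100 * adj / tot
}

#' Select the number of retained factorial axes
#'
#' Axes are retained in order while their adjusted inertia share stays at
#' or above the threshold; at least 2 axes are always retained (the
#' modality maps are 2-dimensional).
#'
#' @param mca A `clbp_mca`, or a numeric vector of per-axis percentages.
#' @param min_marginal_pct Retention threshold in percent.
#' @return Integer K.
#' @export
select_axes <- function(mca, min_marginal_pct = 5) {
  shares <- if (inherits(mca, "clbp_mca")) mca$adjusted_inertia_pct else mca
  K <- 0
  for (s in shares) {
    if (s >= min_marginal_pct) K <- K + 1 else break
  }
  min(max(2L, K), length(shares))
}
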