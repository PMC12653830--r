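# IBSI-style texture features from gray-level matrices. All operations work
# on a 2D integer level image where 0 marks out-of-mask pixels and 1..Ng are
# gray levels (see fbs_discretize). In-plane directions for GLCM/GLRLM are
# (0,1), (1,0), (1,1), (1,-1); features are computed per direction and
# averaged. Degenerate conventions on a constant region: GLCM correlation 1,
# information measures 0, NGTDM coarseness capped at 1e6, all contrasts and
# entropies 0, uniformity-type measures 1.

.texture_dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

level_image <- function(pixels, mask, bin_width) {
  stopifnot(all(dim(pixels) == dim(mask)))
  vals <- pixels[mask]
  lev <- fbs_discretize(vals, bin_width)
  out <- matrix(0L, nrow(pixels), ncol(pixels))
  out[mask] <- lev
  attr(out, "ng") <- attr(lev, "ng")
  out
}

safe_div <- function(num, den, value = 0) if (den == 0) value else num / den

#' Gray-level co-occurrence features
#'
#' Symmetric GLCM at distance 1 over the four in-plane directions, one
#' feature value per direction, then averaged. Returns 22 features (the
#' reference radiomics default: the redundant dissimilarity and sum-average
#' measures are excluded).
#'
#' @param levels Integer level image (0 = outside mask).
#' @param ng Number of gray levels; defaults to `attr(levels, "ng")`.
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(levels, ng = attr(levels, "ng")) {
  if (is.null(ng)) ng <- max(levels)
  per_dir <- lapply(.texture_dirs, function(d) {
    P <- cpp_glcm(levels, ng, d[1], d[2])
    glcm_features_one(P, ng)
  })
  Reduce(`+`, per_dir) / length(per_dir)
}

glcm_features_one <- function(P, ng) {
  if (sum(P) == 0) P[1, 1] <- 1  # lone pixel without neighbours: degenerate
  tot <- sum(P)
  nzi <- which(P != 0)
  pv <- P[nzi] / tot                    # sparse joint probabilities
  iv <- ((nzi - 1) %% ng) + 1
  jv <- ((nzi - 1) %/% ng) + 1
  px <- as.vector(rowsum(pv, iv, reorder = TRUE))  # marginal (symmetric)
  pxi <- sort(unique(iv))
  mu <- sum(iv * pv)
  sigma2 <- sum((iv - mu)^2 * pv)
  dv <- abs(iv - jv)
  p_diff <- rowsum(pv, dv, reorder = TRUE)
  k_diff <- sort(unique(dv))
  sv <- iv + jv
  p_sum <- rowsum(pv, sv, reorder = TRUE)
  da <- sum(k_diff * p_diff)
  hxy <- -sum(pv * log2(pv))
  hx <- -sum(px * log2(px))
  eps <- .Machine$double.eps
  ppij <- px[match(iv, pxi)] * px[match(jv, pxi)]
  hxy1 <- -sum(pv * log2(ppij + eps))
  ppx <- outer(px, px)
  hxy2 <- -sum(ppx * log2(ppx + eps))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sigma2 > 0) (sum(iv * jv * pv) - mu^2) / sigma2 else 1
  offd <- dv > 0
  c(Autocorrelation = sum(iv * jv * pv),
    JointAverage = mu,
    ClusterProminence = sum((iv + jv - 2 * mu)^4 * pv),
    ClusterShade = sum((iv + jv - 2 * mu)^3 * pv),
    ClusterTendency = sum((iv + jv - 2 * mu)^2 * pv),
    Contrast = sum(dv^2 * pv),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff * log2(p_diff)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(pv^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(pv / (1 + dv^2)),
    Idmn = sum(pv / (1 + (dv / ng)^2)),
    Id = sum(pv / (1 + dv)),
    Idn = sum(pv / (1 + dv / ng)),
    InverseVariance = sum(pv[offd] / dv[offd]^2),
    MaximumProbability = max(pv),
    SumEntropy = -sum(p_sum * log2(p_sum)),
    SumSquares = sigma2)
}

# Shared machinery for run/zone/dependence matrices: P is Ng x K with K the
# run length / zone size / dependence, np the number of masked pixels.
rlm_type_features <- function(P, np, tags) {
  ng <- nrow(P)
  nzi <- which(P != 0)
  rlm_type_features_sparse(((nzi - 1) %% ng) + 1, ((nzi - 1) %/% ng) + 1,
                           P[nzi], np, tags)
}

# iv = gray level, jv = run length / zone size / dependence, cv = count
rlm_type_features_sparse <- function(iv, jv, cv, np, tags) {
  nr <- sum(cv)
  if (nr == 0) {
    out <- rep(0, 16)
    names(out) <- tags
    return(out)
  }
  pr <- cv / nr
  ri <- as.vector(rowsum(cv, iv))
  rj <- as.vector(rowsum(cv, jv))
  mu_i <- sum(iv * pr)
  mu_j <- sum(jv * pr)
  vals <- c(
    sum(cv / jv^2) / nr,                  # small emphasis
    sum(cv * jv^2) / nr,                  # large emphasis
    sum(ri^2) / nr,                       # gray-level non-uniformity
    sum(ri^2) / nr^2,                     # gray-level non-uniformity normalized
    sum(rj^2) / nr,                       # size/run non-uniformity
    sum(rj^2) / nr^2,                     # size/run non-uniformity normalized
    nr / np,                              # percentage
    sum((iv - mu_i)^2 * pr),              # gray-level variance
    sum((jv - mu_j)^2 * pr),              # size/run variance
    -sum(pr * log2(pr)),                  # entropy
    sum(cv / iv^2) / nr,                  # low gray-level emphasis
    sum(cv * iv^2) / nr,                  # high gray-level emphasis
    sum(cv / (iv^2 * jv^2)) / nr,         # small + low
    sum(cv * iv^2 / jv^2) / nr,           # small + high
    sum(cv * jv^2 / iv^2) / nr,           # large + low
    sum(cv * iv^2 * jv^2) / nr)           # large + high
  names(vals) <- tags
  vals
}

#' Gray-level run-length features
#'
#' 16 features from the run-length matrix, averaged over the four in-plane
#' directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(levels, ng = attr(levels, "ng")) {
  if (is.null(ng)) ng <- max(levels)
  np <- sum(levels > 0)
  tags <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
            "RunLengthNonUniformityNormalized", "RunPercentage",
            "GrayLevelVariance", "RunVariance", "RunEntropy",
            "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
            "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
            "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  per_dir <- lapply(.texture_dirs, function(d) {
    P <- cpp_glrlm(levels, ng, d[1], d[2])
    rlm_type_features(P, np, tags = tags)
  })
  Reduce(`+`, per_dir) / length(per_dir)
}

#' Gray-level size-zone features
#'
#' 16 features from the size-zone matrix (8-connected zones of equal level).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(levels, ng = attr(levels, "ng")) {
  if (is.null(ng)) ng <- max(levels)
  np <- sum(levels > 0)
  tags <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
            "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
            "SizeZoneNonUniformityNormalized", "ZonePercentage",
            "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
            "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
            "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
            "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  z <- cpp_glszm_zones(levels)
  if (nrow(z) == 0)
    return(rlm_type_features_sparse(integer(0), integer(0), numeric(0), np,
                                    tags))
  agg <- rowsum(rep(1, nrow(z)), paste(z[, 1], z[, 2]))
  key <- do.call(rbind, strsplit(rownames(agg), " "))
  rlm_type_features_sparse(as.integer(key[, 1]), as.integer(key[, 2]),
                           as.vector(agg), np, tags)
}

#' Gray-level dependence features
#'
#' 14 features from the dependence matrix (8-neighbourhood, distance 1,
#' tolerance `alpha`). The dependence index counts the centre pixel plus its
#' dependent neighbours, so it is always at least 1.
#'
#' @inheritParams glcm_features
#' @param alpha Gray-level difference tolerance (default 0).
#' @return Named numeric vector of length 14.
#' @export
gldm_features <- function(levels, ng = attr(levels, "ng"), alpha = 0L) {
  if (is.null(ng)) ng <- max(levels)
  np <- sum(levels > 0)
  P <- cpp_gldm(levels, ng, alpha)
  tags16 <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "DependenceNonUniformity", "DependenceNonUniformityNormalized",
              "DependencePercentage", "GrayLevelVariance",
              "DependenceVariance", "DependenceEntropy",
              "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
              "SmallDependenceLowGrayLevelEmphasis",
              "SmallDependenceHighGrayLevelEmphasis",
              "LargeDependenceLowGrayLevelEmphasis",
              "LargeDependenceHighGrayLevelEmphasis")
  v <- rlm_type_features(P, np, tags = tags16)
  # every pixel yields a dependence entry, so the percentage and the
  # normalized gray-level non-uniformity are uninformative: drop them to
  # obtain the standard 14-feature set
  v[setdiff(tags16, c("GrayLevelNonUniformityNormalized",
                      "DependencePercentage"))]
}

#' Neighbouring gray-tone difference features
#'
#' The five NGTDM features (coarseness, contrast, busyness, complexity,
#' strength) from per-level occurrence counts and summed absolute
#' differences to the 8-neighbourhood mean.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(levels, ng = attr(levels, "ng")) {
  if (is.null(ng)) ng <- max(levels)
  NS <- cpp_ngtdm(levels, ng)
  n_i <- NS[, 1]
  s_i <- NS[, 2]
  nvp <- sum(n_i)
  if (nvp == 0)
    return(c(Coarseness = 1e6, Contrast = 0, Busyness = 0, Complexity = 0,
             Strength = 0))
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  ps <- sum(p_i * s_i)
  coarseness <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  if (ngp > 1) {
    ii <- matrix(act, ngp, ngp)
    jj <- t(ii)
    pi_m <- matrix(p_i[act], ngp, ngp)
    pj_m <- t(pi_m)
    contrast <- sum(pi_m * pj_m * (ii - jj)^2) / (ngp * (ngp - 1)) *
      sum(s_i) / nvp
    busy_den <- sum(abs(ii * pi_m - jj * pj_m))
    busyness <- safe_div(ps, busy_den, 0)
    si_m <- matrix(s_i[act], ngp, ngp)
    sj_m <- t(si_m)
    complexity <- sum(abs(ii - jj) * (pi_m * si_m + pj_m * sj_m) /
                        (pi_m + pj_m)) / nvp
    strength <- safe_div(sum((pi_m + pj_m) * (ii - jj)^2), sum(s_i), 0)
  } else {
    contrast <- busyness <- complexity <- strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
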