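#' Standardized per-breed expression profiles along the domestication order
#'
#' Per-gene mean log-normalized expression in the fixed breed order
#' AWB -> JH -> DU (wild boar -> local breed -> intensive breed), row
#' z-scored. Zero-variance rows are dropped before standardization and
#' reported via the `dropped` attribute.
#'
#' @param lognorm Log-normalized genes x cells matrix.
#' @param breeds Per-cell breed labels.
#' @param cells Optional cell subset (indices, barcodes or logical mask).
#' @param order Condition order of the domestication series.
#' @return Genes x conditions matrix (rows mean 0, sd 1) with attributes
#'   `order` and `dropped`.
#' @export
breed_profile <- function(lognorm, breeds, cells = NULL,
                          order = c("AWB", "JH", "DU")) {
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, colnames(lognorm))
    lognorm <- lognorm[, cells, drop = FALSE]
    breeds <- breeds[cells]
  }
  if (!all(order %in% breeds)) stopf("missing breed in subset: %s",
                                     paste(setdiff(order, breeds), collapse = ", "))
  prof <- vapply(order, function(b)
    Matrix::rowMeans(lognorm[, breeds == b, drop = FALSE]),
    numeric(nrow(lognorm)))
  pop_sd <- function(p) sqrt(rowMeans((p - rowMeans(p))^2))
  keep <- pop_sd(prof) > 0
  dropped <- rownames(prof)[!keep]
  prof <- prof[keep, , drop = FALSE]
  # population-sd standardization: a monotone 3-point profile maps to
  # (-1.2247, 0, 1.2247)
  prof <- (prof - rowMeans(prof)) / pop_sd(prof)
  attr(prof, "order") <- order
  attr(prof, "dropped") <- dropped
  prof
}

#' Empirical fuzzifier estimate
#'
#' The empirical formula for the fuzzy c-means fuzzifier as a function of
#' the number of features `n_genes` (N) and data dimensionality
#' `n_conditions` (D):
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#'
#' @param n_genes Number of profiles to cluster (>= 2).
#' @param n_conditions Profile dimensionality (>= 2).
#' @return Fuzzifier `m > 1`.
#' @export
estimate_fuzzifier <- function(n_genes, n_conditions) {
  if (n_genes < 2 || n_conditions < 2)
    stopf("need n_genes >= 2 and n_conditions >= 2")
  N <- n_genes; D <- n_conditions
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means soft clustering
#'
#' Alternating optimization of the fuzzy c-means objective with Euclidean
#' distance: memberships `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))`,
#' centroids as membership^m-weighted means, iterated until the largest
#' membership change drops below `tol`. The objective is non-increasing
#' across iterations; a run hitting `max_iter` returns with
#' `converged = FALSE` and a warning.
#'
#' @param x Profiles x conditions matrix (e.g. [breed_profile()]).
#' @param centers Number of clusters `c` (default 9, the published
#'   setting).
#' @param m Fuzzifier > 1; default [estimate_fuzzifier()] on `dim(x)`.
#' @param tol Convergence tolerance on memberships.
#' @param max_iter Iteration cap.
#' @param seed Integer seed (random centroid initialization).
#' @return List of class `fuzzy_cmeans`: `centers` (c x conditions),
#'   `membership` (rows sum to 1), `m`, `objective` (per-iteration
#'   trace), `hard` (argmax labels), `converged`, `iterations`.
#' @export
fuzzy_cmeans <- function(x, centers = 9, m = NULL, tol = 1e-6,
                         max_iter = 1000, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (centers >= n) stopf("centers must be smaller than the number of rows")
  if (centers < 2) stopf("need at least 2 centers")
  m <- m %||% estimate_fuzzifier(n, ncol(x))
  if (m <= 1) stopf("fuzzifier m must be > 1")
  set.seed(seed)
  # classic initialization: random data rows as starting centroids (with a
  # small jitter so no centroid coincides exactly with a data point), so
  # the first membership update is distance-driven and stable for any m
  cent <- x[sample.int(n, centers), , drop = FALSE] +
    rnorm(centers * ncol(x), sd = 1e-4 * (sd(x) + 1e-12))
  x2 <- rowSums(x^2)
  obj <- numeric(0)
  converged <- FALSE
  U <- NULL
  memberships_from <- function(d2) {
    zero <- d2 < .Machine$double.eps
    newU <- d2^(-1 / (m - 1))
    newU <- newU / rowSums(newU)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      newU[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    newU
  }
  for (it in seq_len(max_iter)) {
    d2 <- outer(x2, rowSums(cent^2), "+") - 2 * x %*% t(cent)
    d2 <- pmax(d2, 0)
    newU <- memberships_from(d2)
    obj <- c(obj, sum(newU^m * d2))
    delta <- if (is.null(U)) Inf else max(abs(newU - U))
    U <- newU
    if (delta < tol) { converged <- TRUE; break }
    Um <- U^m
    cent <- crossprod(Um, x) / colSums(Um)
  }
  if (!converged) warnf("fuzzy c-means did not converge in %d iterations",
                        max_iter)
  dimnames(U) <- list(rownames(x), paste0("C", seq_len(centers)))
  dimnames(cent) <- list(paste0("C", seq_len(centers)), colnames(x))
  structure(list(centers = cent, membership = U, m = m, objective = obj,
                 hard = max.col(U, ties.method = "first"),
                 converged = converged, iterations = length(obj)),
            class = "fuzzy_cmeans")
}

#' Minimum centroid distance over a range of cluster numbers
#'
#' Runs [fuzzy_cmeans()] for each candidate `c` and records the minimum
#' pairwise Euclidean distance among centroids (Dmin). A plateau near
#' zero indicates redundant clusters; the table is advisory and the
#' published setting `c = 9` stays the default elsewhere.
#'
#' @param x Profiles x conditions matrix.
#' @param m Fuzzifier (default [estimate_fuzzifier()]).
#' @param c_range Candidate cluster numbers, within `[2, nrow(x) - 1]`.
#' @param seed Integer seed.
#' @return `data.frame` with columns `c` and `dmin`.
#' @export
min_centroid_distance <- function(x, m = NULL, c_range = 2:12, seed = 1L) {
  x <- as.matrix(x)
  if (any(c_range < 2) || any(c_range > nrow(x) - 1))
    stopf("c_range must lie in [2, %d]", nrow(x) - 1)
  m <- m %||% estimate_fuzzifier(nrow(x), ncol(x))
  dmin <- vapply(c_range, function(cc) {
    fit <- fuzzy_cmeans(x, centers = cc, m = m, seed = seed)
    min(dist(fit$centers))
  }, numeric(1))
  data.frame(c = c_range, dmin = dmin)
}

# Shape of a 3-point centroid (a, b, c) = (AWB, JH, DU); exact ties give
# no class.
centroid_shape <- function(v) {
  a <- v[1]; b <- v[2]; c <- v[3]
  if (a == b || b == c) return("none")
  if (a < b && b < c) return("increasing")
  if (a > b && b > c) return("decreasing")
  if (b > a && b > c) return("JH-high")
  if (b < a && b < c) return("JH-low")
  "none"
}

#' Classify genes into domestication expression patterns
#'
#' Intersects the soft clustering of breed profiles with differential-
#' expression evidence to call four patterns along AWB -> JH -> DU:
#' `type1` (increasing; requires a sign-consistent DEG call in at least
#' one JH comparison: up in JH vs AWB or down in JH vs DU), `type2`
#' (JH-high; up-DEG in both JH vs AWB and JH vs DU), `type3` (JH-low;
#' down-DEG in both), `type4` (decreasing; down in JH vs AWB or up in
#' JH vs DU). A gene must additionally reach `membership_min` in a
#' shape-consistent cluster; everything else is `none`.
#'
#' @param fit A [fuzzy_cmeans()] result on [breed_profile()] rows.
#' @param deg_jh_awb,deg_jh_du [wilcoxon_deg()] tables with JH as group A.
#' @param membership_min Minimum membership for a cluster assignment
#'   (default 0.5).
#' @return `data.frame`, one row per clustered gene: `gene`, `cluster`,
#'   `membership`, `shape`, `pattern`.
#' @export
classify_patterns <- function(fit, deg_jh_awb, deg_jh_du,
                              membership_min = 0.5) {
  genes <- rownames(fit$membership)
  if (is.null(genes)) stopf("membership matrix must carry gene names")
  shapes <- apply(fit$centers, 1, centroid_shape)
  deg_dir <- function(tab) {
    d <- setNames(ifelse(tab$deg, tab$direction, "ns"), tab$gene)
    out <- d[genes]
    out[is.na(out)] <- "ns"
    out
  }
  da <- deg_dir(deg_jh_awb)   # JH vs AWB
  dd <- deg_dir(deg_jh_du)    # JH vs DU
  j <- fit$hard
  memb <- fit$membership[cbind(seq_along(genes), j)]
  shape <- shapes[j]
  pattern <- rep("none", length(genes))
  ok <- memb >= membership_min
  pattern[ok & shape == "increasing" & (da == "up" | dd == "down")] <- "type1"
  pattern[ok & shape == "JH-high" & da == "up" & dd == "up"] <- "type2"
  pattern[ok & shape == "JH-low" & da == "down" & dd == "down"] <- "type3"
  pattern[ok & shape == "decreasing" & (da == "down" | dd == "up")] <- "type4"
  data.frame(gene = genes, cluster = j, membership = as.numeric(memb),
             shape = shape, pattern = pattern,
             deg_jh_awb = da, deg_jh_du = dd,
             stringsAsFactors = FALSE, row.names = NULL)
}
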