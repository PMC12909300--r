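#' Founder-dosage association scan
#'
#' Tests each marker for an additive association between founder-of-origin
#' dosages and a quantitative trait: a likelihood-ratio test of the linear
#' model with the 8 founder-dosage columns (one dropped for
#' identifiability, since rows sum to 2) added to the covariate design,
#' against the covariates-only null. The LOD score is
#' \eqn{LRT / (2 \ln 10)}. Permutation p-values come from
#' [adaptive_permutation_p()], permuting the trait vector.
#'
#' @param trait Numeric per-animal trait values (no missing values).
#' @param dosages List of markers; each element a list with `marker_id`
#'   and `dosages`, an animals x 8 matrix with rows summing to 2.
#' @param covariates Optional numeric design matrix (animals x p) of
#'   nuisance covariates (diet, cohort); an intercept is always included.
#' @param max_perm,target_exceed Adaptive permutation controls.
#' @param seed Integer seed; marker m uses `seed + m`.
#'
#' @return Data frame: `marker_id`, `lrt_stat`, `lod`, `p_perm`,
#'   `n_perm_used`.
#' @export
founder_scan <- function(trait, dosages, covariates = NULL,
                         max_perm = 10000, target_exceed = 10, seed = 1) {
  n <- length(trait)
  if (any(is.na(trait))) stop("trait must have no missing values")
  X0 <- cbind(intercept = rep(1, n), covariates)
  q0 <- qr(X0)
  out <- vector("list", length(dosages))
  for (m in seq_along(dosages)) {
    D <- dosages[[m]]$dosages
    stopifnot(nrow(D) == n, ncol(D) == 8)
    X1 <- cbind(X0, D[, -1, drop = FALSE])  # drop first founder column
    q1 <- qr(X1)
    stat_fun <- function(y) {
      rss0 <- sum(qr.resid(q0, y)^2)
      rss1 <- sum(qr.resid(q1, y)^2)
      if (rss0 <= 1e-12) return(0)   # degenerate (constant) trait
      if (rss1 <= 1e-12) return(Inf) # perfect fit under the full model
      n * log(rss0 / rss1)
    }
    lrt <- stat_fun(trait)
    if (!is.finite(lrt) || lrt < 0) lrt <- 0
    pp <- adaptive_permutation_p(lrt, function(y_perm) stat_fun(y_perm),
                                 trait, max_perm = max_perm,
                                 target_exceed = target_exceed,
                                 seed = seed + m)
    out[[m]] <- data.frame(marker_id = dosages[[m]]$marker_id,
                           lrt_stat = lrt, lod = lrt / (2 * log(10)),
                           p_perm = pp$p, n_perm_used = pp$n_used)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Adaptive sequential permutation p-value
#'
#' Permutes the trait vector and recomputes the test statistic until
#' either `target_exceed` permuted statistics meet or exceed the observed
#' one or `max_perm` permutations have been used, then reports
#' \eqn{p = (1 + \#exceed) / (1 + \#perm)}. Early stopping spends
#' permutations where they matter: strong signals run to the cap, null
#' markers stop after a handful. Deterministic given the seed.
#'
#' @param observed_stat Observed test statistic.
#' @param stat_fn Function mapping a permuted trait vector to the
#'   statistic.
#' @param trait The trait vector to permute.
#' @param max_perm Permutation cap (>= 100).
#' @param target_exceed Exceedance count triggering early stop.
#' @param seed Integer seed.
#'
#' @return List with `p` and `n_used`.
#' @export
adaptive_permutation_p <- function(observed_stat, stat_fn, trait,
                                   max_perm = 10000, target_exceed = 10,
                                   seed = 1) {
  if (max_perm < 100) stop("max_perm must be at least 100")
  set.seed(seed)
  n_exceed <- 0L
  n_used <- 0L
  while (n_used < max_perm && n_exceed < target_exceed) {
    y <- sample(trait)
    n_used <- n_used + 1L
    if (stat_fn(y) >= observed_stat) n_exceed <- n_exceed + 1L
  }
  list(p = (1 + n_exceed) / (1 + n_used), n_used = n_used)
}

#' Cluster-specific FDR genome-wide significance threshold
#'
#' Implements the clustered false-discovery procedure for correlated
#' phenotypes. Within each phenotype cluster: (1) per variant,
#' Benjamini-Hochberg across the cluster's phenotypes at `alpha` marks
#' significant phenotype associations; (2) each variant is assigned one
#' sampled p-value — drawn from all its phenotype p-values if none were
#' significant, from the significant subset otherwise; (3) BH across
#' variants on the sampled vector at `alpha` gives the cluster threshold,
#' the largest sampled p-value passing. The study-wide threshold is the
#' minimum across clusters (0 when nothing passes anywhere).
#'
#' @param P Matrix of p-values, variants x phenotypes, entries in (0, 1].
#' @param clusters Vector of cluster labels, one per phenotype column.
#' @param alpha FDR level (default 0.05).
#' @param seed Integer seed for the p-value sampling.
#'
#' @return List with `study_threshold` and `cluster_thresholds` (named).
#' @export
cluster_fdr_threshold <- function(P, clusters, alpha = 0.05, seed = 1) {
  P <- as.matrix(P)
  if (any(P <= 0 | P > 1)) stop("p-values must lie in (0, 1]")
  if (length(clusters) != ncol(P))
    stop("clusters must label every phenotype column")
  set.seed(seed)
  thr <- stats::setNames(rep(NA_real_, length(unique(clusters))),
                         unique(clusters))
  for (cl in unique(clusters)) {
    Pc <- P[, clusters == cl, drop = FALSE]
    sampled <- apply(Pc, 1, function(pv) {
      adj <- stats::p.adjust(pv, method = "BH")
      pool <- if (any(adj <= alpha)) pv[adj <= alpha] else pv
      pool[sample.int(length(pool), 1)]
    })
    adj_v <- stats::p.adjust(sampled, method = "BH")
    pass <- sampled[adj_v <= alpha]
    thr[cl] <- if (length(pass) > 0) max(pass) else 0
  }
  list(study_threshold = min(thr), cluster_thresholds = thr)
}

#' Group fine-mapped variants by founder-allele pattern
#'
#' For each biallelic variant the minor allele is the one carried by the
#' smaller set of founder strains (a 4-vs-4 split resolves to the
#' lexicographically smaller set); its founder set is the variant's FAP.
#' Variants sharing a FAP form a group; groups are ranked by the largest
#' LOD score among their member variants. Variants whose allele is carried
#' by zero or all eight founders are non-segregating and excluded.
#'
#' @param variants Data frame with columns `variant_id`, `pos_bp`, `lod`,
#'   and `founders_alt`: a list-column (or "/"-separated string column) of
#'   the founders carrying the alternate allele.
#'
#' @return Data frame of groups, ranked: `rank`, `pattern`
#'   ("/"-separated founder set), `n_variants`, `max_lod`, `top_variant`,
#'   `start_bp`, `end_bp`.
#' @export
fap_group_variants <- function(variants) {
  founders <- DO_FOUNDERS
  parse_set <- function(x) {
    s <- if (is.character(x)) strsplit(x, "/", fixed = TRUE)[[1]]
    else as.character(unlist(x))
    founders[founders %in% s]  # canonical founder order
  }
  recs <- list()
  for (i in seq_len(nrow(variants))) {
    alt <- parse_set(variants$founders_alt[i])
    if (length(alt) == 0 || length(alt) == 8) next  # non-segregating
    ref <- setdiff(founders, alt)
    minor <- if (length(alt) < length(ref)) alt
    else if (length(ref) < length(alt)) ref
    else {
      # 4-vs-4 split: lexicographically smaller founder set
      a <- paste(sort(alt), collapse = "/")
      r <- paste(sort(ref), collapse = "/")
      if (a <= r) alt else ref
    }
    recs[[length(recs) + 1]] <- data.frame(
      variant_id = variants$variant_id[i], pos_bp = variants$pos_bp[i],
      lod = variants$lod[i], pattern = paste(minor, collapse = "/"))
  }
  if (length(recs) == 0)
    return(data.frame(rank = integer(0), pattern = character(0),
                      n_variants = integer(0), max_lod = numeric(0),
                      top_variant = character(0), start_bp = numeric(0),
                      end_bp = numeric(0)))
  df <- do.call(rbind, recs)
  groups <- do.call(rbind, lapply(split(df, df$pattern), function(g) {
    k <- which.max(g$lod)
    data.frame(pattern = g$pattern[1], n_variants = nrow(g),
               max_lod = max(g$lod),
               top_variant = as.character(g$variant_id[k]),
               start_bp = min(g$pos_bp), end_bp = max(g$pos_bp))
  }))
  groups <- groups[order(-groups$max_lod), ]
  groups <- cbind(rank = seq_len(nrow(groups)), groups)
  rownames(groups) <- NULL
  groups
}

#' Cluster phenotypes by their correlation structure
#'
#' Convenience helper: average-linkage hierarchical clustering of
#' `1 - |cor|` distances, cut into `k` groups. The study's genetic
#' correlation clustering is an input; this mirrors it for synthetic runs.
#'
#' @param trait_matrix Animals x phenotypes numeric matrix.
#' @param k Number of clusters (default 2).
#'
#' @return Integer cluster label per phenotype column.
#' @export
cluster_phenotypes <- function(trait_matrix, k = 2) {
  cc <- stats::cor(trait_matrix, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - abs(cc))
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}
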