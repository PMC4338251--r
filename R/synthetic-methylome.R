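#' Default per-archetype methylation targets for the 24 planted HMR clusters
#'
#' Rows are the 24 cluster archetypes (8 promoter "A", 8 intragenic "B", 8
#' intergenic "C"), columns the seven sample archetypes of the default study
#' design (one normal breast, one benign tumour, two invasive carcinomas,
#' one normal-derived and two cancer cell lines). Entries are target
#' methylation levels. The patterns mirror the qualitative cluster behaviour
#' in breast methylomes: a constitutively open cluster (x-1), clusters
#' hypermethylated specifically in tumours or cell lines, clusters
#' hypomethylated only in cell lines, and an XCI-like cluster (x-8) at 50%
#' in females but unmethylated in XCI-lost cell lines.
#'
#' @param samples sample names (columns); length 7 by default.
#' @return numeric matrix, 24 x length(samples), rownames "A-1".."C-8".
#' @export
default_cluster_profiles <- function(samples = c("NB", "BT089", "BT126",
                                                 "BT198", "HMEC", "MCF7",
                                                 "HCC1954")) {
  base <- rbind(
    c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),  # constitutive low
    c(0.05, 0.10, 0.45, 0.50, 0.10, 0.50, 0.45),  # hyper in invasive+cancer
    c(0.05, 0.05, 0.40, 0.45, 0.05, 0.80, 0.80),  # hyper in cancer lines
    c(0.10, 0.45, 0.45, 0.10, 0.80, 0.10, 0.45),  # mixed
    c(0.45, 0.45, 0.10, 0.10, 0.45, 0.05, 0.10),  # hypo in cancer
    c(0.05, 0.05, 0.80, 0.80, 0.05, 0.85, 0.85),  # strong cancer hyper
    c(0.80, 0.80, 0.45, 0.45, 0.10, 0.10, 0.10),  # hypo in cell lines
    c(0.50, 0.50, 0.50, 0.45, 0.50, 0.05, 0.05))  # XCI-like
  if (length(samples) != ncol(base)) {
    stop("default profiles are defined for ", ncol(base), " samples")
  }
  m <- rbind(base, base, base)
  rownames(m) <- paste0(rep(c("A", "B", "C"), each = 8), "-", rep(1:8, 3))
  colnames(m) <- samples
  m
}

#' Sample-archetype specification for methylome simulation
#'
#' @param name one of `"normal"`, `"benign"`, `"invasive"`, `"cell_line"`,
#'   `"male_like"`; presets fill the remaining arguments.
#' @param background_level genome-wide background methylation (the mostly
#'   methylated state, ~0.75-0.8).
#' @param hmr_level generic hypomethylated-region level, used for planted
#'   sites with no cluster profile entry.
#' @param pmd_level methylation inside partially methylated domains.
#' @param pmd_fraction target fraction of the genome converted to PMDs
#'   (candidate desert blocks are recruited until the target is met).
#' @param pmd_blocks optional explicit PMD block `interval_set`, overriding
#'   `pmd_fraction`.
#' @param cluster_profiles named numeric vector mapping cluster archetype
#'   ids ("A-1".."C-8") to target levels for this sample; defaults to the
#'   matching column of [default_cluster_profiles()].
#' @param mean_depth mean reads per CpG (default 19, the ~19x design);
#'   `Inf` gives the noiseless infinite-depth limit.
#' @param dispersion beta-binomial overdispersion rho in \[0, 1); 0 gives
#'   level = target exactly (no sampling of the methylated fraction).
#' @param x_promoter_level override level for X-linked gene promoters (0.5
#'   for an XCI-intact female, low for male-like or XCI-lost samples);
#'   `NULL` disables the override.
#' @param xist_level level of the XIST promoter (moves opposite to the
#'   other X promoters: ~0.5 allelic when XCI is intact, hypermethylated
#'   when XCI is lost).
#' @param profile_column column of [default_cluster_profiles()] to use.
#' @return list of class `archetype_spec`.
#' @export
archetype_spec <- function(name = "normal",
                           background_level = NULL, hmr_level = 0.05,
                           pmd_level = 0.45, pmd_fraction = NULL,
                           pmd_blocks = NULL, cluster_profiles = NULL,
                           mean_depth = 19, dispersion = 0.08,
                           x_promoter_level = NULL, xist_level = NULL,
                           profile_column = NULL) {
  presets <- list(
    normal    = list(bg = 0.78, pmd = 0.00, xp = 0.5, xist = 0.5, col = "NB"),
    benign    = list(bg = 0.77, pmd = 0.005, xp = 0.5, xist = 0.5, col = "BT089"),
    invasive  = list(bg = 0.75, pmd = 0.10, xp = 0.5, xist = 0.5, col = "BT126"),
    cell_line = list(bg = 0.72, pmd = 0.30, xp = 0.05, xist = 0.9, col = "MCF7"),
    male_like = list(bg = 0.78, pmd = 0.00, xp = 0.05, xist = 0.9, col = "NB"))
  if (!name %in% names(presets)) {
    stop("unknown archetype name: ", name)
  }
  p <- presets[[name]]
  spec <- list(
    name = name,
    background_level = background_level %||% p$bg,
    hmr_level = hmr_level,
    pmd_level = pmd_level,
    pmd_fraction = pmd_fraction %||% p$pmd,
    pmd_blocks = pmd_blocks,
    cluster_profiles = cluster_profiles,
    mean_depth = mean_depth,
    dispersion = dispersion,
    x_promoter_level = x_promoter_level %||% p$xp,
    xist_level = xist_level %||% p$xist,
    profile_column = profile_column %||% p$col)
  lv <- c(spec$background_level, spec$hmr_level, spec$pmd_level)
  if (any(lv < 0 | lv > 1)) stop("archetype levels must lie in [0,1]")
  if (!(spec$mean_depth > 0)) stop("mean_depth must be positive")
  if (spec$dispersion < 0 || spec$dispersion >= 1) {
    stop("dispersion must lie in [0,1)")
  }
  class(spec) <- "archetype_spec"
  spec
}

#' Simulate a per-CpG methylome for one sample archetype
#'
#' Builds the planted piecewise-constant level function (background, PMD
#' blocks, planted HMR sites at their cluster-profile targets, X-promoter
#' and XIST overrides), then adds WGBS-style count noise: reads per CpG ~
#' Poisson(mean_depth) and the methylated fraction beta-binomial around the
#' regional target. Planted truth (HMR and PMD intervals with labels) is
#' returned alongside the track for use as a test oracle; it is never
#' embedded in the track itself.
#'
#' @param genome a `genome_annotation`.
#' @param archetype an [archetype_spec()].
#' @param seed integer seed.
#' @param sample_id label for the track.
#' @return list with elements `track` (a `methylome`) and `truth` (list:
#'   `hmrs` interval set with `category`/`cluster`/`level` columns, `pmds`
#'   interval set, `background_level`).
#' @export
generate_methylome <- function(genome, archetype, seed = 1,
                               sample_id = archetype$name) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(archetype, "archetype_spec"))
  with_seed(seed, .generate_methylome_impl(genome, archetype, sample_id))
}

.generate_methylome_impl <- function(genome, arch, sample_id) {
  profiles <- arch$cluster_profiles
  if (is.null(profiles)) {
    pm <- default_cluster_profiles()
    profiles <- stats::setNames(pm[, arch$profile_column], rownames(pm))
  }

  # choose PMD blocks from the candidate deserts
  pmds <- arch$pmd_blocks
  if (is.null(pmds)) {
    pmds <- .recruit_pmd_blocks(genome, arch$pmd_fraction)
  }

  sites <- as.data.frame(genome$hmr_sites)
  cat_letter <- c(promoter = "A", intragenic = "B", intergenic = "C")
  key <- paste0(cat_letter[sites$category], "-", sites$cluster)
  site_level <- unname(profiles[key])
  site_level[is.na(site_level)] <- arch$hmr_level

  # X-inactivation overrides on X-linked promoters
  if (!is.null(arch$x_promoter_level)) {
    xg <- genome$genes$id[genome$genes$is_x_linked]
    on_x_prom <- sites$category == "promoter" & sites$gene_id %in% xg
    site_level[on_x_prom] <- arch$x_promoter_level
    xist <- xist_gene_id(genome)
    site_level[sites$gene_id %in% xist] <- arch$xist_level
  }
  sites$level <- site_level

  chroms <- genome$chromosomes
  track_parts <- list()
  for (ci in seq_len(nrow(chroms))) {
    chrom <- chroms$name[ci]
    pos <- genome$cpg_positions[[chrom]]
    m <- rep(arch$background_level, length(pos))
    p <- pmds[pmds$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(p))) {
      m[pos >= p$start[j] & pos < p$end[j]] <- arch$pmd_level
    }
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(s))) {
      m[pos >= s$start[j] & pos < s$end[j]] <- s$level[j]
    }
    noised <- .bb_noise(m, arch$mean_depth, arch$dispersion)
    track_parts[[ci]] <- data.frame(chrom = chrom, pos = pos,
                                    level = noised$level,
                                    reads = noised$reads,
                                    stringsAsFactors = FALSE)
  }
  tp <- do.call(rbind, track_parts)
  track <- methylome(chrom = tp$chrom, pos = tp$pos, level = tp$level,
                     reads = tp$reads, sample_id = sample_id)
  truth_hmrs <- as_interval_set(
    sites[order(sites$chrom, sites$start),
          c("chrom", "start", "end", "category", "cluster", "level",
            "gene_id", "site_id")])
  list(track = track,
       truth = list(hmrs = truth_hmrs, pmds = pmds,
                    background_level = arch$background_level))
}

# Beta-binomial count noise. dispersion rho maps to a beta precision
# s = (1 - rho) / rho; rho = 0 means the methylated fraction equals the
# target exactly. Infinite depth returns the (possibly beta-noised) target
# as the observed level.
.bb_noise <- function(m, mean_depth, dispersion) {
  n <- length(m)
  p <- if (dispersion > 0) {
    s <- (1 - dispersion) / dispersion
    stats::rbeta(n, clamp01(m) * s, (1 - clamp01(m)) * s)
  } else m
  if (is.infinite(mean_depth)) {
    return(list(level = p, reads = rep(1e6, n)))
  }
  reads <- stats::rpois(n, mean_depth)
  meth <- stats::rbinom(n, reads, p)
  level <- ifelse(reads > 0, meth / reads, NA_real_)
  list(level = level, reads = reads)
}

.recruit_pmd_blocks <- function(genome, fraction) {
  cand <- as.data.frame(genome$pmd_candidates)
  if (fraction <= 0 || nrow(cand) == 0) {
    return(interval_set())
  }
  total <- sum(genome$chromosomes$length)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  w <- cand$end - cand$start
  # greedy: keep adding while it brings the coverage closer to the target
  target <- fraction * total
  covered <- 0; take <- integer()
  for (i in seq_len(nrow(cand))) {
    if (abs(covered + w[i] - target) < abs(covered - target)) {
      take <- c(take, i); covered <- covered + w[i]
    }
  }
  if (!length(take)) take <- which.min(w)
  sort_intervals(as_interval_set(cand[take, c("chrom", "start", "end")]))
}

#' The designated XIST-like gene of a synthetic genome
#'
#' The first X-linked gene is reserved as the XIST stand-in.
#'
#' @param genome a `genome_annotation`.
#' @return gene id (character), or `NA` if the genome has no X-linked gene.
#' @export
xist_gene_id <- function(genome) {
  xg <- genome$genes$id[genome$genes$is_x_linked]
  if (length(xg) == 0) return(NA_character_)
  xg[1]
}

#' Simulate a reference-HMR methylation matrix from planted cluster profiles
#'
#' Draws `n_per_cluster` reference HMRs per cluster archetype and, per
#' sample, a region-level methylation value: the coverage-weighted mean of
#' `n_cpg` beta-binomial CpG draws around the profile target. This is the
#' region-level shortcut for atlas-clustering experiments; the full per-CpG
#' route is [generate_methylome()] + [score_reference()].
#'
#' @param profiles matrix as from [default_cluster_profiles()].
#' @param n_per_cluster reference HMRs per cluster archetype.
#' @param n_cpg CpGs per region.
#' @param mean_depth reads per CpG.
#' @param dispersion beta-binomial overdispersion.
#' @param seed integer seed.
#' @return list: `matrix` (regions x samples), `cluster` (planted archetype
#'   id per row), `category` (location class per row).
#' @export
simulate_atlas_matrix <- function(profiles = default_cluster_profiles(),
                                  n_per_cluster = 100, n_cpg = 15,
                                  mean_depth = 19, dispersion = 0.08,
                                  seed = 1) {
  with_seed(seed, {
    n_row <- nrow(profiles) * n_per_cluster
    cl <- rep(rownames(profiles), each = n_per_cluster)
    m <- matrix(NA_real_, n_row, ncol(profiles),
                dimnames = list(sprintf("ref%05d", seq_len(n_row)),
                                colnames(profiles)))
    row_of <- rep(seq_len(n_row), each = n_cpg)
    for (j in seq_len(ncol(profiles))) {
      target <- rep(rep(profiles[, j], each = n_per_cluster), each = n_cpg)
      noised <- .bb_noise(target, mean_depth, dispersion)
      lvl <- noised$level; rd <- noised$reads
      rd[is.na(lvl)] <- 0; lvl[is.na(lvl)] <- 0
      num <- rowsum(lvl * rd, row_of); den <- rowsum(rd, row_of)
      m[, j] <- ifelse(den > 0, num / den, NA_real_)
    }
    list(matrix = m, cluster = cl,
         category = substr(cl, 1, 1))
  })
}
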