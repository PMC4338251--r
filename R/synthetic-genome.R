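#' Configuration for the synthetic genome generator
#'
#' Describes a small stand-in genome: a handful of chromosomes (one X-like),
#' CpG-dense islands at most promoters, CpG-poor gene deserts that serve as
#' candidate blocks for partially methylated domains, and planted HMR sites
#' in the three genomic location classes (promoter / intragenic /
#' intergenic), each carrying one of eight cluster archetypes per class.
#'
#' @param chromosomes data.frame with `name` and `length` (bp); must include
#'   one chromosome whose name contains "X".
#' @param n_genes total gene count, allocated to chromosomes by length.
#' @param background_density CpGs per bp outside islands and deserts.
#' @param desert_density CpGs per bp inside gene deserts (CpG-poor).
#' @param cgi_density CpGs per bp inside CpG islands.
#' @param cgi_width width of a promoter CpG island (bp).
#' @param promoter_halfwidth promoter = TSS +/- this many bp.
#' @param desert_fraction fraction of each chromosome reserved as gene
#'   desert (PMD candidate blocks).
#' @param cgi_promoter_fraction fraction of promoters carrying a CGI.
#' @param intragenic_sites,intergenic_sites planted non-promoter HMR sites.
#' @param n_clusters archetype clusters per location class.
#' @return list of class `genome_config`.
#' @export
genome_config <- function(chromosomes = data.frame(
                            name = c("chr1", "chr2", "chrX"),
                            length = c(4e6, 3e6, 4e6)),
                          n_genes = 150,
                          background_density = 0.01,
                          desert_density = 0.004,
                          cgi_density = 0.10,
                          cgi_width = 1000,
                          promoter_halfwidth = 1000,
                          desert_fraction = 0.40,
                          cgi_promoter_fraction = 0.8,
                          intragenic_sites = 60,
                          intergenic_sites = 60,
                          n_clusters = 8) {
  cfg <- list(chromosomes = chromosomes, n_genes = n_genes,
              background_density = background_density,
              desert_density = desert_density, cgi_density = cgi_density,
              cgi_width = cgi_width, promoter_halfwidth = promoter_halfwidth,
              desert_fraction = desert_fraction,
              cgi_promoter_fraction = cgi_promoter_fraction,
              intragenic_sites = intragenic_sites,
              intergenic_sites = intergenic_sites, n_clusters = n_clusters)
  if (any(chromosomes$length < 10 * 2 * promoter_halfwidth)) {
    stop("invalid genome config: chromosome shorter than 10x promoter width")
  }
  if (!any(grepl("X", chromosomes$name))) {
    stop("invalid genome config: no X-like chromosome")
  }
  class(cfg) <- "genome_config"
  cfg
}

#' Generate a synthetic genome annotation
#'
#' Deterministic for a fixed seed. Returns chromosome sizes, sorted CpG
#' positions, CpG islands, gene models (TSS, span, strand, X-linked flag),
#' planted HMR sites labelled with location class and cluster archetype,
#' gene-desert blocks (PMD candidates), fragile-site-like blocks, eight
#' synthetic regulatory feature tracks, and chromatin-state segments for two
#' cell-type archetypes. Every gene promoter (TSS +/- 1 kb) is guaranteed to
#' contain at least 5 CpGs.
#'
#' @param config a [genome_config()].
#' @param seed integer seed.
#' @return list of class `genome_annotation`.
#' @export
generate_genome <- function(config = genome_config(), seed = 1) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(seed, .generate_genome_impl(config, seed))
}

.generate_genome_impl <- function(cfg, seed) {
  chroms <- cfg$chromosomes
  genes_per_chrom <- .allocate_counts(cfg$n_genes, chroms$length)

  genes <- list(); deserts <- list(); cgis <- list()
  hmr_sites <- list(); cpg_pos <- list()

  for (ci in seq_len(nrow(chroms))) {
    chrom <- chroms$name[ci]; clen <- chroms$length[ci]
    is_x <- grepl("X", chrom)

    # gene deserts: non-overlapping blocks totalling ~desert_fraction
    des <- .place_desert_blocks(clen, cfg$desert_fraction)
    deserts[[ci]] <- if (nrow(des)) cbind(chrom = chrom, des) else NULL

    # genes placed in non-desert space
    ng <- genes_per_chrom[ci]
    gdf <- .place_genes(chrom, clen, des, ng, cfg$promoter_halfwidth, is_x)
    if (nrow(gdf) == 0) gdf$has_cgi <- logical(0)
    genes[[ci]] <- gdf

    # promoter CGIs for a fraction of genes
    if (nrow(gdf)) {
      has_cgi <- stats::runif(nrow(gdf)) < cfg$cgi_promoter_fraction
      gdf$has_cgi <- has_cgi
      genes[[ci]] <- gdf
      cg <- gdf[has_cgi, , drop = FALSE]
      if (nrow(cg)) {
        cgis[[ci]] <- data.frame(
          chrom = chrom,
          start = pmax(0, cg$tss - cfg$cgi_width / 2),
          end = pmin(clen, cg$tss + cfg$cgi_width / 2))
      }
    }
  }
  genes <- do.call(rbind, genes)
  genes$id <- sprintf("gene%04d", seq_len(nrow(genes)))
  deserts <- do.call(rbind, deserts)

  # planted HMR sites: every promoter is a site; intragenic sites inside
  # long gene bodies; intergenic sites in gene-free, non-desert space
  prom <- if (nrow(genes)) {
    data.frame(chrom = genes$chrom,
               start = pmax(0, genes$tss - 500),
               end = genes$tss + 500,
               category = "promoter", gene_id = genes$id,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               category = character(), gene_id = character(),
               stringsAsFactors = FALSE)
  }
  intra <- .place_intragenic_sites(genes, cfg$intragenic_sites)
  inter <- .place_intergenic_sites(chroms, genes, deserts,
                                   cfg$intergenic_sites)
  sites <- rbind(prom, intra, inter)
  # planted sites must stay separable: drop sites within 2 kb of a kept one
  # (promoters take precedence), so each planted HMR is its own truth region
  sites <- sites[.thin_sites(sites, min_gap = 2000), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  # cluster assignment: round-robin within each location class
  sites$cluster <- rep(NA_integer_, nrow(sites))
  for (cat in unique(sites$category)) {
    idx <- which(sites$category == cat)
    sites$cluster[idx] <- (seq_along(idx) - 1L) %% cfg$n_clusters + 1L
  }
  sites$site_id <- if (nrow(sites)) sprintf("site%05d", seq_len(nrow(sites))) else character()
  genes$promoter_cluster <- sites$cluster[match(genes$id, sites$gene_id)]

  # CpG positions: piecewise-constant Poisson process
  cgis_df <- do.call(rbind, cgis)
  for (ci in seq_len(nrow(chroms))) {
    chrom <- chroms$name[ci]; clen <- chroms$length[ci]
    # CpG-dense windows: CGIs plus every planted site not already under a
    # promoter CGI (so all planted HMRs have island-like CpG density)
    cgi_genes <- genes$id[genes$has_cgi %||% rep(FALSE, nrow(genes))]
    under_cgi <- sites$category == "promoter" & sites$gene_id %in% cgi_genes
    pos <- .sample_cpgs(clen,
                        base = cfg$background_density,
                        deserts = deserts[deserts$chrom == chrom, ],
                        desert_density = cfg$desert_density,
                        dense = rbind(
                          cgis_df[cgis_df$chrom == chrom, c("start", "end")],
                          sites[sites$chrom == chrom & !under_cgi,
                                c("start", "end")]),
                        dense_density = cfg$cgi_density)
    # guarantee >= 5 CpGs per promoter
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(g)) {
      for (j in seq_len(nrow(g))) {
        lo <- max(0, g$tss[j] - cfg$promoter_halfwidth)
        hi <- min(clen, g$tss[j] + cfg$promoter_halfwidth)
        n_in <- sum(pos >= lo & pos < hi)
        if (n_in < 5) {
          pos <- c(pos, round(seq(lo + 50, hi - 50, length.out = 5 - n_in + 2)))
        }
      }
    }
    cpg_pos[[chrom]] <- sort(unique(round(pos)))
  }

  fragile <- .pick_blocks(deserts, fraction = 0.3)

  ann <- list(
    chromosomes = chroms,
    cpg_positions = cpg_pos,
    cgis = if (is.null(cgis_df)) interval_set() else
      sort_intervals(as_interval_set(cgis_df)),
    genes = genes,
    hmr_sites = as_interval_set(sites),
    pmd_candidates = if (is.null(deserts)) interval_set() else
      sort_intervals(as_interval_set(deserts)),
    fragile_blocks = fragile,
    config = cfg, seed = seed)
  ann$feature_sets <- .build_feature_sets(ann)
  ann$state_segments <- .build_state_segments(ann)
  class(ann) <- "genome_annotation"
  ann
}

.thin_sites <- function(sites, min_gap) {
  n <- nrow(sites)
  if (n == 0) return(logical(0))
  pri <- ifelse(sites$category == "promoter", 0L, 1L)
  ord <- order(pri, sites$chrom, sites$start)
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (sites$chrom[j] == sites$chrom[i] &&
          sites$start[i] < sites$end[j] + min_gap &&
          sites$end[i] > sites$start[j] - min_gap) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

.allocate_counts <- function(n, weights) {
  raw <- n * weights / sum(weights)
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    extra <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[extra] <- out[extra] + 1
  }
  out
}

.place_desert_blocks <- function(clen, fraction) {
  target <- clen * fraction
  if (target < 1e5) return(data.frame(start = numeric(), end = numeric()))
  blocks <- list(); covered <- 0; guard <- 0
  w_lo <- min(3e5, clen * 0.06); w_hi <- min(9e5, clen * 0.15)
  while (covered < target && guard < 300) {
    guard <- guard + 1
    w <- stats::runif(1, w_lo, w_hi)
    if (w >= clen) break
    s <- round(stats::runif(1, 0, clen - w))
    pad <- min(5e4, clen * 0.02)
    ok <- TRUE
    for (b in blocks) if (s < b[2] + pad && s + w > b[1] - pad) ok <- FALSE
    if (ok) { blocks[[length(blocks) + 1]] <- c(s, round(s + w)); covered <- covered + w }
  }
  if (!length(blocks)) return(data.frame(start = numeric(), end = numeric()))
  m <- do.call(rbind, blocks)
  data.frame(start = m[, 1], end = m[, 2])[order(m[, 1]), , drop = FALSE]
}

.place_genes <- function(chrom, clen, deserts, n, prom_hw, is_x) {
  if (n == 0) {
    return(data.frame(chrom = character(), strand = character(),
                      tss = numeric(), start = numeric(), end = numeric(),
                      is_x_linked = logical(), stringsAsFactors = FALSE))
  }
  # candidate slots on a jittered grid, rejected if inside a desert
  slots <- round(seq(prom_hw * 2, clen - prom_hw * 2, length.out = n * 3))
  slots <- slots + round(stats::runif(length(slots), -2000, 2000))
  pad <- max(1e4, min(5e4, clen * 0.02))
  in_desert <- rep(FALSE, length(slots))
  if (nrow(deserts)) {
    for (j in seq_len(nrow(deserts))) {
      in_desert <- in_desert |
        (slots > deserts$start[j] - pad & slots < deserts$end[j] + pad)
    }
  }
  slots <- slots[!in_desert]
  if (length(slots) == 0) {
    return(data.frame(chrom = character(), strand = character(),
                      tss = numeric(), start = numeric(), end = numeric(),
                      is_x_linked = logical(), stringsAsFactors = FALSE))
  }
  slots <- slots[seq(1, length(slots), length.out = min(n, length(slots)))]
  strand <- sample(c("+", "-"), length(slots), replace = TRUE)
  span <- round(stats::runif(length(slots), 5e3, 4e4))
  tss <- round(slots)
  start <- ifelse(strand == "+", tss, pmax(0, tss - span))
  end <- ifelse(strand == "+", pmin(clen, tss + span), tss)
  bad <- start >= end
  data.frame(chrom = chrom, strand = strand, tss = tss,
             start = start, end = end, is_x_linked = is_x,
             stringsAsFactors = FALSE)[!bad, , drop = FALSE]
}

.place_intragenic_sites <- function(genes, n) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), category = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (n == 0 || nrow(genes) == 0) return(empty)
  long <- genes[genes$end - genes$start >= 1.2e4, , drop = FALSE]
  if (nrow(long) == 0) return(empty)
  pick <- long[sample.int(nrow(long), n, replace = n > nrow(long)), ]
  # body position well away from the TSS-side promoter
  w <- round(stats::runif(n, 800, 1500))
  lo <- ifelse(pick$strand == "+", pick$tss + 4000, pick$start + 1000)
  hi <- ifelse(pick$strand == "+", pick$end - 1000, pick$tss - 4000) - w
  s <- round(lo + stats::runif(n) * pmax(1, hi - lo))
  data.frame(chrom = pick$chrom, start = s, end = s + w,
             category = "intragenic", gene_id = pick$id,
             stringsAsFactors = FALSE)
}

.place_intergenic_sites <- function(chroms, genes, deserts, n) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), category = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  out <- list(); tries <- 0
  blocked <- rbind(
    data.frame(chrom = genes$chrom, start = genes$start - 2000,
               end = genes$end + 2000),
    if (!is.null(deserts) && nrow(deserts))
      data.frame(chrom = deserts$chrom, start = deserts$start - 1e4,
                 end = deserts$end + 1e4))
  while (length(out) < n && tries < n * 30) {
    tries <- tries + 1
    ci <- sample.int(nrow(chroms), 1)
    w <- round(stats::runif(1, 800, 2000))
    s <- round(stats::runif(1, 0, chroms$length[ci] - w))
    b <- blocked[blocked$chrom == chroms$name[ci], , drop = FALSE]
    if (!is.finite(s)) next
    if (!any(s < b$end & s + w > b$start, na.rm = TRUE)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = chroms$name[ci], start = s, end = s + w,
        category = "intergenic", gene_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

.sample_cpgs <- function(clen, base, deserts, desert_density,
                         dense, dense_density) {
  pos <- sort(stats::runif(stats::rpois(1, clen * base), 0, clen))
  if (!is.null(deserts) && nrow(deserts)) {
    keep_p <- rep(1, length(pos))
    for (j in seq_len(nrow(deserts))) {
      inside <- pos >= deserts$start[j] & pos < deserts$end[j]
      keep_p[inside] <- desert_density / base
    }
    pos <- pos[stats::runif(length(pos)) < keep_p]
  }
  if (!is.null(dense) && nrow(dense)) {
    for (j in seq_len(nrow(dense))) {
      w <- dense$end[j] - dense$start[j]
      extra <- stats::runif(stats::rpois(1, w * dense_density),
                            dense$start[j], dense$end[j])
      pos <- c(pos, extra)
    }
  }
  sort(pos)
}

.pick_blocks <- function(deserts, fraction) {
  if (is.null(deserts) || nrow(deserts) == 0) return(interval_set())
  n <- max(1, round(nrow(deserts) * fraction))
  idx <- seq(1, nrow(deserts), length.out = n)
  sort_intervals(as_interval_set(deserts[unique(round(idx)),
                                         c("chrom", "start", "end")]))
}

# Eight synthetic regulatory feature tracks. Sites in clusters 1 and 6 of
# each class draw many features (high regulatory potential, like A-1/A-6);
# other clusters draw few. Background intervals keep the tracks from being
# pure site markers.
.build_feature_sets <- function(ann) {
  feats <- c("fantom5_tss", "fantom5_enhancer", "cgi", "encode_tfbs",
             "dnase", "mnase_hs", "hpaii_hs", "polii")
  sites <- ann$hmr_sites
  out <- stats::setNames(vector("list", length(feats)), feats)
  n_feat_per_site <- ifelse(sites$cluster %in% c(1L, 6L),
                            sample(5:8, nrow(sites), replace = TRUE),
                            sample(0:5, nrow(sites), replace = TRUE))
  pick <- lapply(seq_len(nrow(sites)), function(i) {
    sample(feats, n_feat_per_site[i])
  })
  for (f in feats) {
    has <- vapply(pick, function(p) f %in% p, logical(1))
    df <- sites[has, c("chrom", "start", "end"), drop = FALSE]
    # jitter so features are not byte-identical to the sites
    if (nrow(df)) {
      df$start <- pmax(0, df$start + round(stats::runif(nrow(df), -200, 200)))
      df$end <- df$end + round(stats::runif(nrow(df), -200, 200))
      df <- df[df$start < df$end, , drop = FALSE]
    }
    bg <- .random_background_intervals(ann$chromosomes, n = 40,
                                       w_range = c(200, 1500))
    out[[f]] <- merge_intervals(as_interval_set(rbind(df, bg)))
  }
  out$cgi <- merge_intervals(as_interval_set(rbind(
    as.data.frame(ann$cgis)[, c("chrom", "start", "end")],
    as.data.frame(out$cgi)[, c("chrom", "start", "end")])))
  out
}

.random_background_intervals <- function(chroms, n, w_range) {
  ci <- sample.int(nrow(chroms), n, replace = TRUE)
  w <- round(stats::runif(n, w_range[1], w_range[2]))
  s <- round(stats::runif(n) * (chroms$length[ci] - w))
  data.frame(chrom = chroms$name[ci], start = s, end = s + w,
             stringsAsFactors = FALSE)
}

# Chromatin-state segments for two cell-type archetypes. Promoter states sit
# on promoter sites; enhancer states on archetype-specific cluster subsets
# (so cluster/state enrichment is planted); heterochromatin on the deserts.
.build_state_segments <- function(ann) {
  sites <- ann$hmr_sites
  mk <- function(enh_clusters) {
    prom <- sites[sites$category == "promoter", c("chrom", "start", "end")]
    enh <- sites[sites$category != "promoter" &
                   sites$cluster %in% enh_clusters,
                 c("chrom", "start", "end")]
    het <- as.data.frame(ann$pmd_candidates)[, c("chrom", "start", "end")]
    list(promoter = merge_intervals(as_interval_set(prom)),
         enhancer = merge_intervals(as_interval_set(enh)),
         heterochromatin = merge_intervals(as_interval_set(het)))
  }
  list(hmec_like = mk(c(4L, 7L, 8L)), mcf7_like = mk(c(4L, 5L, 7L)))
}
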