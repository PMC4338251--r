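#' Coverage-weighted mean methylation level
#'
#' The regional methylation level used throughout: sum(level * reads) /
#' sum(reads) over CpGs with at least one read. CpGs with zero coverage
#' carry an undefined level and are excluded, never counted as 0.
#'
#' @param level per-CpG methylation levels (NA allowed).
#' @param reads per-CpG read counts.
#' @return weighted mean in \[0, 1\], or `NA_real_` when no CpG is
#'   assessable.
#' @export
weighted_mean_level <- function(level, reads) {
  ok <- !is.na(level) & reads > 0
  if (!any(ok)) return(NA_real_)
  sum(level[ok] * reads[ok]) / sum(reads[ok])
}

#' Count CpGs in low / intermediate / high methylation categories
#'
#' Boundaries follow the usual three-band summary: low < 20%, high > 80%,
#' intermediate otherwise (both 0.2 and 0.8 land in the intermediate band).
#'
#' @param track a `methylome`.
#' @param regions optional `interval_set`; when given only CpGs inside the
#'   regions are counted (e.g. restrict to CGIs).
#' @return named integer vector `c(low, intermediate, high)`; the three
#'   counts sum to the number of assessable CpGs considered.
#' @export
level_categories <- function(track, regions = NULL) {
  lvl <- track$level
  keep <- !is.na(lvl)
  if (!is.null(regions)) {
    if (nrow(regions) == 0) {
      return(c(low = 0L, intermediate = 0L, high = 0L))
    }
    cpg <- interval_set(track$chrom, track$pos, track$pos + 1)
    keep <- keep & overlaps_any(cpg, regions)
  }
  lvl <- lvl[keep]
  c(low = sum(lvl < 0.2),
    intermediate = sum(lvl >= 0.2 & lvl <= 0.8),
    high = sum(lvl > 0.8))
}

#' Tile the genome into fixed windows and summarise methylation and CpG
#' density
#'
#' @param track a `methylome`.
#' @param genome a `genome_annotation` or chromosome data.frame.
#' @param window_size window width in bp.
#' @return data.frame: chrom, start, end, mean_level (coverage-weighted;
#'   NA when the window has no assessable CpG), n_cpg, cpg_density (CpGs
#'   per 100 bp).
#' @export
window_summary <- function(track, genome, window_size = 10000) {
  stopifnot(window_size > 0)
  chroms <- genome_chromosomes(genome)
  out <- list()
  for (ci in seq_len(nrow(chroms))) {
    chrom <- chroms$name[ci]; clen <- chroms$length[ci]
    starts <- seq(0, clen - 1, by = window_size)
    ends <- pmin(starts + window_size, clen)
    t <- track[track$chrom == chrom, , drop = FALSE]
    win <- findInterval(t$pos, starts)
    n_cpg <- tabulate(win, nbins = length(starts))
    ok <- !is.na(t$level)
    num <- rowsum(ifelse(ok, t$level * t$reads, 0), win,
                  reorder = FALSE)
    den <- rowsum(ifelse(ok, t$reads, 0), win, reorder = FALSE)
    mean_level <- rep(NA_real_, length(starts))
    widx <- as.integer(rownames(num))
    mean_level[widx] <- ifelse(den[, 1] > 0, num[, 1] / den[, 1], NA_real_)
    out[[ci]] <- data.frame(chrom = chrom, start = starts, end = ends,
                            mean_level = mean_level, n_cpg = n_cpg,
                            cpg_density = n_cpg / ((ends - starts) / 100),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# Two-state hidden Markov segmentation.
#
# Emissions: beta-binomial with state means (m_lo, m_hi) and a shared
# precision; the binomial coefficient is state-independent and dropped.
# Parameters are fitted by EM with a deterministic histogram split
# initialisation (low state = mean of observations below the midpoint of
# the observed range); posterior decoding at 0.5. Chromosomes are
# fragmented at CpG gaps exceeding max_gap BEFORE decoding, so no emitted
# region can span such a gap.
# ---------------------------------------------------------------------------

.bb_loglik <- function(meth, total, m, s) {
  a <- m * s; b <- (1 - m) * s
  lbeta(meth + a, total - meth + b) - lbeta(a, b)
}

.gauss_loglik <- function(x, m, sd) stats::dnorm(x, m, sd, log = TRUE)

# Forward-backward with scaling over one fragment; e = likelihood matrix
# (T x 2), A = transition matrix, pi = initial distribution.
.forward_backward <- function(e, A, pi) {
  n <- nrow(e)
  alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2); cvec <- numeric(n)
  a <- pi * e[1, ]; cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% A) * e[t, ]
    cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    b <- A %*% (e[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # expected transition counts
  xi <- matrix(0, 2, 2)
  for (t in 2:n) {
    x <- (alpha[t - 1, ] %o% (e[t, ] * beta[t, ])) * A / cvec[t]
    xi <- xi + x
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)))
}

# Fit the two-state chain over a list of fragments.
# obs: list with per-fragment emission-loglik closure and sufficient stats.
.fit_two_state <- function(frags, loglik_fun, update_fun, init,
                           max_iter = 25, tol = 1e-4) {
  par <- init
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  pi <- c(0.5, 0.5)
  last_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    gammas <- vector("list", length(frags))
    xi <- matrix(0, 2, 2); pi_acc <- c(0, 0); ll <- 0
    for (fi in seq_along(frags)) {
      fr <- frags[[fi]]
      if (nrow(fr) == 1) {
        ll1 <- loglik_fun(fr, par)
        e <- exp(ll1 - max(ll1))
        g <- matrix(pi * e / sum(pi * e), 1, 2)
        gammas[[fi]] <- g; pi_acc <- pi_acc + g[1, ]
        next
      }
      llm <- loglik_fun(fr, par)            # T x 2 log-likelihoods
      shift <- apply(llm, 1, max)
      e <- exp(llm - shift)
      fb <- .forward_backward(e, A, pi)
      gammas[[fi]] <- fb$gamma
      xi <- xi + fb$xi
      pi_acc <- pi_acc + fb$gamma[1, ]
      ll <- ll + fb$loglik + sum(shift)
    }
    par <- update_fun(frags, gammas, par)
    if (sum(xi) > 0) {
      A <- xi / rowSums(xi)
      A <- pmin(pmax(A, 1e-6), 1 - 1e-6)
      A <- A / rowSums(A)
    }
    pi <- pi_acc / sum(pi_acc)
    pi <- pmin(pmax(pi, 1e-6), 1)
    pi <- pi / sum(pi)
    if (is.finite(ll) && abs(ll - last_ll) < tol * abs(last_ll + 1)) break
    last_ll <- ll
  }
  # final posteriors
  gammas <- vector("list", length(frags))
  for (fi in seq_along(frags)) {
    fr <- frags[[fi]]
    llm <- loglik_fun(fr, par)
    if (nrow(fr) == 1) {
      e <- exp(llm - max(llm))
      gammas[[fi]] <- matrix(pi * e / sum(pi * e), 1, 2)
    } else {
      e <- exp(llm - apply(llm, 1, max))
      gammas[[fi]] <- .forward_backward(e, A, pi)$gamma
    }
  }
  list(par = par, A = A, pi = pi, gammas = gammas)
}

# Split indices into fragments wherever consecutive positions are more than
# max_gap apart (and at chromosome changes).
.fragment_indices <- function(chrom, pos, max_gap) {
  n <- length(pos)
  if (n == 0) return(list())
  brk <- c(TRUE, chrom[-1] != chrom[-n] | diff(pos) > max_gap)
  split(seq_len(n), cumsum(brk))
}

# Contiguous TRUE runs -> (from, to) index pairs.
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(from = starts[r$values], to = ends[r$values])
}

#' Call hypomethylated regions (HMRs)
#'
#' Segments the per-CpG track into low/high methylation states with a
#' two-state beta-binomial hidden Markov model (EM-fitted, deterministic
#' initialisation, posterior decoding at 0.5). Chromosomes are fragmented
#' at CpG gaps larger than `max_cpg_gap` before decoding, so no HMR ever
#' contains an internal CpG gap above the limit. Low-state runs with at
#' least `min_cpg` CpGs and mean level below `level_ceiling` are emitted.
#'
#' @param track a `methylome`.
#' @param max_cpg_gap maximum CpG distance inside one region (default
#'   1000 bp, the 1 kb rule).
#' @param min_cpg minimum CpGs per HMR (default 4).
#' @param precision beta-binomial precision of the emission model.
#' @param max_iter EM iteration cap.
#' @param min_separation if the fitted state means are closer than this,
#'   the track is considered HMR-free (guards against splitting pure
#'   noise).
#' @param level_ceiling emitted regions must have mean level below this.
#' @return `interval_set` with columns `n_cpg`, `mean_level`; sorted and
#'   disjoint. `sample_id` attribute propagated from the track.
#' @export
call_hmrs <- function(track, max_cpg_gap = 1000, min_cpg = 4,
                      precision = 10, max_iter = 25,
                      min_separation = 0.2, level_ceiling = 0.5) {
  t <- track[!is.na(track$level) & track$reads > 0, , drop = FALSE]
  if (nrow(t) < min_cpg) {
    warning("track has fewer than min_cpg assessable CpGs; no HMRs called")
    return(.empty_region_set(c("n_cpg", "mean_level")))
  }
  meth <- round(t$level * t$reads)
  frag_idx <- .fragment_indices(t$chrom, t$pos, max_cpg_gap)
  frags <- lapply(frag_idx, function(ix) {
    data.frame(meth = meth[ix], total = t$reads[ix], level = t$level[ix])
  })

  mid <- (min(t$level) + max(t$level)) / 2
  init <- list(m = c(mean(t$level[t$level < mid]),
                     mean(t$level[t$level >= mid])))
  init$m[is.nan(init$m)] <- c(0.05, 0.85)[is.nan(init$m)]

  loglik_fun <- function(fr, par) {
    cbind(.bb_loglik(fr$meth, fr$total, clamp01(par$m[1]), precision),
          .bb_loglik(fr$meth, fr$total, clamp01(par$m[2]), precision))
  }
  update_fun <- function(frags, gammas, par) {
    num <- c(0, 0); den <- c(0, 0)
    for (fi in seq_along(frags)) {
      fr <- frags[[fi]]; g <- gammas[[fi]]
      num <- num + colSums(g * fr$meth)
      den <- den + colSums(g * fr$total)
    }
    m <- ifelse(den > 0, num / den, par$m)
    list(m = sort(m))  # keep state 1 = low
  }
  fit <- .fit_two_state(frags, loglik_fun, update_fun, init, max_iter)

  if (diff(fit$par$m) < min_separation) {
    return(.empty_region_set(c("n_cpg", "mean_level"),
                             sample_id = attr(track, "sample_id")))
  }
  regions <- list()
  for (fi in seq_along(frags)) {
    ix <- frag_idx[[fi]]
    low <- fit$gammas[[fi]][, 1] > 0.5
    if (!any(low)) next
    runs <- .runs(low)
    for (r in seq_len(nrow(runs))) {
      sel <- ix[runs[r, "from"]:runs[r, "to"]]
      if (length(sel) < min_cpg) next
      ml <- weighted_mean_level(t$level[sel], t$reads[sel])
      if (is.na(ml) || ml >= level_ceiling) next
      regions[[length(regions) + 1]] <- data.frame(
        chrom = t$chrom[sel[1]], start = t$pos[sel[1]],
        end = t$pos[sel[length(sel)]] + 2,
        n_cpg = length(sel), mean_level = ml, stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) {
    return(.empty_region_set(c("n_cpg", "mean_level"),
                             sample_id = attr(track, "sample_id")))
  }
  out <- sort_intervals(as_interval_set(do.call(rbind, regions)))
  attr(out, "sample_id") <- attr(track, "sample_id")
  out
}

# Move each domain boundary to the CpG position that best splits the local
# window into a high-state outside and a low-state inside (binomial
# likelihood under the fitted state means).
.refine_pmd_boundaries <- function(merged, t, par, window_bp) {
  m_lo <- min(max(par$m[1], 0.01), 0.99)
  m_hi <- min(max(par$m[2], 0.01), 0.99)
  for (i in seq_len(nrow(merged))) {
    ch <- merged$chrom[i]
    tt <- t[t$chrom == ch, , drop = FALSE]
    meth <- round(tt$level * tt$reads)
    ll_lo <- stats::dbinom(meth, tt$reads, m_lo, log = TRUE)
    ll_hi <- stats::dbinom(meth, tt$reads, m_hi, log = TRUE)

    refine <- function(b0, is_start) {
      w <- which(tt$pos >= b0 - window_bp & tt$pos < b0 + window_bp)
      n <- length(w)
      if (n < 2) return(b0)
      lo <- ll_lo[w]; hi <- ll_hi[w]
      # candidate k: boundary just before the k-th window CpG (k = n+1:
      # past the last); score the high-outside / low-inside split
      sc <- if (is_start) {
        sum(lo) + cumsum(c(0, hi - lo))
      } else {
        sum(hi) + cumsum(c(0, lo - hi))
      }
      k <- which.max(sc)
      if (is_start) {
        if (k <= n) tt$pos[w[k]] else tt$pos[w[n]] + 1
      } else {
        if (k > 1) tt$pos[w[k - 1]] + 1 else tt$pos[w[1]]
      }
    }
    new_start <- refine(merged$start[i], is_start = TRUE)
    new_end <- refine(merged$end[i], is_start = FALSE)
    if (new_end > new_start) {
      merged$start[i] <- new_start
      merged$end[i] <- new_end
    }
    inside <- which(tt$pos >= merged$start[i] & tt$pos < merged$end[i])
    merged$num[i] <- sum(tt$level[inside] * tt$reads[inside])
    merged$den[i] <- max(1, sum(tt$reads[inside]))
  }
  merged
}

.empty_region_set <- function(extra_cols, sample_id = NULL) {
  df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   stringsAsFactors = FALSE)
  for (cc in extra_cols) df[[cc]] <- numeric()
  out <- as_interval_set(df)
  attr(out, "sample_id") <- sample_id
  out
}

#' Call partially methylated domains (PMDs)
#'
#' Bins each chromosome (default 1 kb), computes coverage-weighted bin
#' means (bins with fewer than `min_cpg_per_bin` CpGs are masked), then
#' runs a two-state Gaussian-emission hidden Markov model over the bin
#' means to separate partially methylated from methylated state. Domains
#' are split at CpG gaps above `max_cpg_gap` (the 20 kb rule), and domains
#' shorter than `min_domain` or with mean level outside
#' (`level_floor`, `level_ceiling`) are discarded.
#'
#' @param track a `methylome`.
#' @param bin_size bin width in bp.
#' @param max_cpg_gap maximum CpG distance inside one domain (20 kb).
#' @param min_domain minimum domain length in bp (default 100 kb).
#' @param min_cpg_per_bin mask bins with fewer CpGs than this.
#' @param max_iter EM iteration cap.
#' @param min_separation minimum fitted state-mean gap; below it the track
#'   is considered PMD-free.
#' @param level_floor,level_ceiling emitted domains must have mean level
#'   strictly inside this band (partially methylated, not HMR-like, not
#'   fully methylated).
#' @param merge_within adjacent decoded domains closer than this (bp) are
#'   merged before the size filter: a couple of noisy bins should not
#'   split a megabase domain into discardable fragments.
#' @return `interval_set` with columns `n_bins`, `mean_level`.
#' @export
call_pmds <- function(track, bin_size = 1000, max_cpg_gap = 20000,
                      min_domain = 1e5, min_cpg_per_bin = 3,
                      max_iter = 25, min_separation = 0.15,
                      level_floor = 0.15, level_ceiling = 0.7,
                      merge_within = 4000) {
  t <- track[!is.na(track$level) & track$reads > 0, , drop = FALSE]
  if (nrow(t) == 0) {
    warning("track has no assessable CpGs; no PMDs called")
    return(.empty_region_set(c("n_bins", "mean_level")))
  }
  bin_id <- paste0(t$chrom, ":", floor(t$pos / bin_size))
  num <- rowsum(t$level * t$reads, bin_id, reorder = FALSE)
  den <- rowsum(t$reads, bin_id, reorder = FALSE)
  cnt <- rowsum(rep(1, nrow(t)), bin_id, reorder = FALSE)
  bins <- data.frame(key = rownames(num),
                     mean = num[, 1] / den[, 1], n_cpg = cnt[, 1],
                     stringsAsFactors = FALSE)
  kp <- strsplit(bins$key, ":", fixed = TRUE)
  bins$chrom <- vapply(kp, `[`, "", 1)
  bins$bin <- as.numeric(vapply(kp, `[`, "", 2))
  bins <- bins[bins$n_cpg >= min_cpg_per_bin, , drop = FALSE]
  bins <- bins[order(bins$chrom, bins$bin), , drop = FALSE]
  if (nrow(bins) < 5) {
    return(.empty_region_set(c("n_bins", "mean_level"),
                             sample_id = attr(track, "sample_id")))
  }
  pos <- bins$bin * bin_size
  frag_idx <- .fragment_indices(bins$chrom, pos, max_cpg_gap)
  frags <- lapply(frag_idx, function(ix) data.frame(x = bins$mean[ix]))

  mid <- (min(bins$mean) + max(bins$mean)) / 2
  m0 <- c(mean(bins$mean[bins$mean < mid]), mean(bins$mean[bins$mean >= mid]))
  m0[is.nan(m0)] <- c(0.45, 0.8)[is.nan(m0)]
  init <- list(m = m0, sd = c(0.08, 0.08))

  loglik_fun <- function(fr, par) {
    cbind(.gauss_loglik(fr$x, par$m[1], par$sd[1]),
          .gauss_loglik(fr$x, par$m[2], par$sd[2]))
  }
  update_fun <- function(frags, gammas, par) {
    num <- c(0, 0); den <- c(0, 0); ss <- c(0, 0)
    for (fi in seq_along(frags)) {
      fr <- frags[[fi]]; g <- gammas[[fi]]
      num <- num + colSums(g * fr$x); den <- den + colSums(g)
    }
    m <- ifelse(den > 0, num / den, par$m)
    o <- order(m); m <- m[o]
    for (fi in seq_along(frags)) {
      fr <- frags[[fi]]; g <- gammas[[fi]][, o, drop = FALSE]
      ss <- ss + colSums(g * (outer(fr$x, m, "-")^2))
    }
    sd <- sqrt(ifelse(den > 0, ss / den[o], par$sd^2))
    list(m = m, sd = pmax(sd, 0.02))
  }
  fit <- .fit_two_state(frags, loglik_fun, update_fun, init, max_iter)

  if (diff(fit$par$m) < min_separation ||
      fit$par$m[1] >= level_ceiling) {
    return(.empty_region_set(c("n_bins", "mean_level"),
                             sample_id = attr(track, "sample_id")))
  }
  raw <- list()
  for (fi in seq_along(frags)) {
    ix <- frag_idx[[fi]]
    low <- fit$gammas[[fi]][, 1] > 0.5
    if (!any(low)) next
    runs <- .runs(low)
    for (r in seq_len(nrow(runs))) {
      sel <- ix[runs[r, "from"]:runs[r, "to"]]
      raw[[length(raw) + 1]] <- data.frame(
        chrom = bins$chrom[sel[1]],
        start = bins$bin[sel[1]] * bin_size,
        end = (bins$bin[sel[length(sel)]] + 1) * bin_size,
        n_bins = length(sel),
        num = sum(bins$mean[sel] * bins$n_cpg[sel]),
        den = sum(bins$n_cpg[sel]), stringsAsFactors = FALSE)
    }
  }
  regions <- list()
  if (length(raw)) {
    raw <- do.call(rbind, raw)
    # only PMD-like pieces take part in merging: low-state runs over
    # hypomethylated regions (HMR-level bins) must not extend a domain
    piece_mean <- raw$num / raw$den
    raw <- raw[piece_mean > level_floor & piece_mean < level_ceiling, ,
               drop = FALSE]
  }
  if (nrow(raw) %||% 0 > 0) {
    raw <- raw[order(raw$chrom, raw$start), , drop = FALSE]
    merged <- raw[1, , drop = FALSE]
    for (i in seq_len(nrow(raw))[-1]) {
      last <- nrow(merged)
      if (raw$chrom[i] == merged$chrom[last] &&
          raw$start[i] - merged$end[last] <= merge_within) {
        merged$end[last] <- raw$end[i]
        merged$n_bins[last] <- merged$n_bins[last] + raw$n_bins[i]
        merged$num[last] <- merged$num[last] + raw$num[i]
        merged$den[last] <- merged$den[last] + raw$den[i]
      } else {
        merged <- rbind(merged, raw[i, ])
      }
    }
    # local changepoint polish: slide each boundary within a small window
    # to the per-CpG split maximizing inside-low / outside-high likelihood
    # (CpG-level, so boundaries can land inside masked bins)
    merged <- .refine_pmd_boundaries(merged, t, fit$par, window_bp = 8000)
    merged$mean_level <- merged$num / merged$den
    keep <- merged$end - merged$start >= min_domain &
      merged$mean_level > level_floor & merged$mean_level < level_ceiling
    merged <- merged[keep, c("chrom", "start", "end", "n_bins",
                             "mean_level"), drop = FALSE]
    regions <- if (nrow(merged)) list(merged) else list()
  }
  if (!length(regions)) {
    return(.empty_region_set(c("n_bins", "mean_level"),
                             sample_id = attr(track, "sample_id")))
  }
  out <- sort_intervals(as_interval_set(do.call(rbind, regions)))
  attr(out, "sample_id") <- attr(track, "sample_id")
  out
}
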