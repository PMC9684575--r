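# Genomic-scar measures of homologous recombination deficiency computed on
# an allele-specific copy-number segment profile: large-scale transitions
# (LST), HRD-LOH, telomeric allelic imbalance (NtAI), and their unweighted
# sum, plus purity-decile summaries.

#' Genome build information
#'
#' Contig lengths and centromere intervals, needed by the telomeric and
#' arm-restriction clauses of the scar scores.
#'
#' @param contigs data.frame with columns contig, length, cen_start, cen_end
#' @return list of class `GenomeBuildInfo`
#' @export
genome_build <- function(contigs) {
  stopifnot(all(c("contig", "length", "cen_start", "cen_end") %in%
                names(contigs)),
            all(contigs$length > 0),
            all(contigs$cen_start >= 1), all(contigs$cen_end >= contigs$cen_start),
            all(contigs$cen_end <= contigs$length))
  structure(list(contigs = as.data.frame(contigs)), class = "GenomeBuildInfo")
}

.build_row <- function(build, contig) {
  i <- match(contig, build$contigs$contig)
  if (is.na(i)) stop("contig not in genome build: ", contig)
  as.list(build$contigs[i, , drop = FALSE])
}

.seg_len <- function(s) s$end - s$start + 1

#' Smooth a segment profile
#'
#' Removes segments shorter than `min_len` (default 3 Mb), then merges
#' consecutive same-contig segments with identical (total_cn, minor_cn)
#' states, bridging any gap left by removed segments. Deterministic.
#'
#' @param profile a [segment_profile()]
#' @param min_len minimum segment length retained, in bp (default 3e6)
#' @return a smoothed `SegmentProfile`
#' @export
smooth_profile <- function(profile, min_len = 3e6) {
  s <- profile$segments
  if (nrow(s) == 0) return(profile)
  s <- s[(s$end - s$start + 1) >= min_len, , drop = FALSE]
  if (nrow(s) > 1) {
    keep <- rep(TRUE, nrow(s))
    for (i in seq(2, nrow(s))) {
      j <- max(which(keep[seq_len(i - 1)]))
      same <- s$contig[i] == s$contig[j] &&
        identical(s$total_cn[i], s$total_cn[j]) &&
        ((is.na(s$minor_cn[i]) && is.na(s$minor_cn[j])) ||
           (!is.na(s$minor_cn[i]) && !is.na(s$minor_cn[j]) &&
              s$minor_cn[i] == s$minor_cn[j]))
      if (same) {
        s$end[j] <- s$end[i]
        keep[i] <- FALSE
      }
    }
    s <- s[keep, , drop = FALSE]
  }
  rownames(s) <- NULL
  profile$segments <- s
  profile
}

# split smoothed segments at the centromere into per-arm pieces
.arm_segments <- function(segments, build) {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- as.list(segments[i, , drop = FALSE])
    b <- .build_row(build, seg$contig)
    p_end <- b$cen_start - 1
    q_start <- b$cen_end + 1
    if (seg$start <= p_end) {
      piece <- seg; piece$end <- min(seg$end, p_end); piece$arm <- "p"
      out[[length(out) + 1L]] <- piece
    }
    if (seg$end >= q_start) {
      piece <- seg; piece$start <- max(seg$start, q_start); piece$arm <- "q"
      out[[length(out) + 1L]] <- piece
    }
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), total_cn = integer(0),
                      minor_cn = integer(0), arm = character(0)))
  do.call(rbind, lapply(out, function(p)
    data.frame(contig = p$contig, start = p$start, end = p$end,
               total_cn = p$total_cn, minor_cn = p$minor_cn, arm = p$arm,
               stringsAsFactors = FALSE)))
}

#' Large-scale transition (LST) score
#'
#' Number of breakpoints between consecutive same-arm segments where both
#' flanking segments are at least `min_flank` (default 10 Mb, arm-clipped)
#' and the allele-specific state (total_cn, minor_cn) changes across the
#' breakpoint. Transitions straddling the centromere do not count. The
#' profile is smoothed (3 Mb) first unless `smooth = FALSE`.
#'
#' @param profile a [segment_profile()]
#' @param build a [genome_build()]
#' @param min_flank flank-length threshold in bp (default 1e7)
#' @param smooth whether to apply [smooth_profile()] first
#' @return integer count
#' @export
lst_score <- function(profile, build, min_flank = 1e7, smooth = TRUE) {
  if (smooth) profile <- smooth_profile(profile)
  arms <- .arm_segments(profile$segments, build)
  if (nrow(arms) < 2) return(0L)
  n <- 0L
  for (key in unique(paste(arms$contig, arms$arm))) {
    a <- arms[paste(arms$contig, arms$arm) == key, , drop = FALSE]
    if (nrow(a) < 2) next
    for (i in seq(2, nrow(a))) {
      state_change <- !identical(a$total_cn[i], a$total_cn[i - 1]) ||
        !identical(a$minor_cn[i], a$minor_cn[i - 1])
      if (state_change &&
          (a$end[i - 1] - a$start[i - 1] + 1) >= min_flank &&
          (a$end[i] - a$start[i] + 1) >= min_flank)
        n <- n + 1L
    }
  }
  n
}

#' HRD-LOH score
#'
#' Number of loss-of-heterozygosity segments (minor copy number 0) longer
#' than `min_len` (default 15 Mb) that do not span their entire chromosome.
#' Segments with missing minor copy number are excluded.
#'
#' @param profile a [segment_profile()]
#' @param build a [genome_build()]
#' @param min_len length threshold in bp (default 1.5e7; strictly greater
#'   counts)
#' @param smooth whether to apply [smooth_profile()] first
#' @return integer count
#' @export
hrd_loh_score <- function(profile, build, min_len = 1.5e7, smooth = TRUE) {
  if (smooth) profile <- smooth_profile(profile)
  s <- profile$segments
  if (nrow(s) == 0) return(0L)
  n <- 0L
  for (i in seq_len(nrow(s))) {
    if (is.na(s$minor_cn[i]) || s$minor_cn[i] != 0) next
    if ((s$end[i] - s$start[i] + 1) <= min_len) next
    b <- .build_row(build, s$contig[i])
    whole <- s$start[i] <= 1 && s$end[i] >= b$length
    if (!whole) n <- n + 1L
  }
  n
}

#' NtAI score (telomeric allelic imbalance)
#'
#' Number of allelically imbalanced segments (2 * minor_cn != total_cn) that
#' reach a chromosome end and do not cross the centromere. Segments with
#' missing minor copy number are excluded.
#'
#' @param profile a [segment_profile()]
#' @param build a [genome_build()]
#' @param smooth whether to apply [smooth_profile()] first
#' @return integer count
#' @export
ntai_score <- function(profile, build, smooth = TRUE) {
  if (smooth) profile <- smooth_profile(profile)
  s <- profile$segments
  if (nrow(s) == 0) return(0L)
  n <- 0L
  for (i in seq_len(nrow(s))) {
    if (is.na(s$minor_cn[i])) next
    if (2 * s$minor_cn[i] == s$total_cn[i]) next
    b <- .build_row(build, s$contig[i])
    telomeric <- s$start[i] <= 1 || s$end[i] >= b$length
    crosses_cen <- s$start[i] < b$cen_start && s$end[i] > b$cen_end
    if (telomeric && !crosses_cen) n <- n + 1L
  }
  n
}

#' HRD-sum and its components
#'
#' Computes LST, HRD-LOH and NtAI on the smoothed profile and returns their
#' unweighted sum.
#'
#' @param profile a [segment_profile()]
#' @param build a [genome_build()]
#' @return list of class `HrdScores`: lst, hrd_loh, ntai, hrd_sum
#' @export
hrd_sum <- function(profile, build) {
  sm <- smooth_profile(profile)
  lst <- lst_score(sm, build, smooth = FALSE)
  loh <- hrd_loh_score(sm, build, smooth = FALSE)
  ntai <- ntai_score(sm, build, smooth = FALSE)
  structure(list(lst = lst, hrd_loh = loh, ntai = ntai,
                 hrd_sum = lst + loh + ntai),
            class = "HrdScores")
}

#' @method print HrdScores
#' @export
print.HrdScores <- function(x, ...) {
  cat(sprintf("HRD scores: LST %d + HRD-LOH %d + NtAI %d = HRD-sum %d\n",
              x$lst, x$hrd_loh, x$ntai, x$hrd_sum))
  invisible(x)
}

#' Purity-decile summary of HRD-sum scores
#'
#' Splits records into 10 equal-size purity-rank bins and reports the
#' median, first and third quartiles of HRD-sum per bin.
#'
#' @param records data.frame with columns `purity` and `hrd_sum`
#'   (at least 10 rows)
#' @return data.frame with decile, n, purity_min, purity_max, q1, median, q3
#' @export
purity_decile_summary <- function(records) {
  stopifnot(all(c("purity", "hrd_sum") %in% names(records)))
  n <- nrow(records)
  if (n < 10) stop("need at least 10 records for a decile summary")
  r <- rank(records$purity, ties.method = "first")
  decile <- ceiling(r * 10 / n)
  out <- lapply(1:10, function(d) {
    x <- records$hrd_sum[decile == d]
    p <- records$purity[decile == d]
    data.frame(decile = d, n = length(x),
               purity_min = min(p), purity_max = max(p),
               q1 = unname(stats::quantile(x, 0.25)),
               median = stats::median(x),
               q3 = unname(stats::quantile(x, 0.75)))
  })
  do.call(rbind, out)
}
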