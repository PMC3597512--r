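# Anchor-centred signal metaprofiles.
#
# A metaprofile averages a per-nucleotide signal track across a set of
# anchors (21U 5'-T positions, transcription start sites, or random
# intergenic windows), orienting each extracted window 5'->3' on the
# anchor strand. Anchors whose window would run off the chromosome are
# skipped, not zero-padded.

#' Random non-overlapping intergenic windows
#'
#' Partitions the unannotated fraction of the genome into random,
#' non-overlapping windows of fixed length; window centres serve as
#' anchors for background profiles.
#'
#' @param annotations data frame of annotated intervals (`chrom`, `start`,
#'   `end`, 1-based inclusive) to exclude; may have zero rows.
#' @param chrom_lengths named integer vector.
#' @param window window length (nt).
#' @param seed random seed.
#' @return data frame of anchors: `chrom`, `start`, `end`, `pos` (window
#'   centre), `strand` (`"+"`). Empty (with a warning) when no unannotated
#'   stretch can hold a window.
#' @export
build_intergenic_windows <- function(annotations, chrom_lengths,
                                     window = 1000L, seed = 1) {
  seed <- check_seed(seed)
  out <- list()
  withr_seed(seed, {
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      free <- rep(TRUE, L)
      ann <- annotations[annotations$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(ann)))
        free[max(1L, ann$start[j]):min(L, ann$end[j])] <- FALSE
      r <- rle(free)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths >= window)
      for (ri in runs) {
        len <- r$lengths[ri]
        k <- len %/% window
        slack <- len - k * window
        # random left offset, then contiguous tiling: non-overlapping and
        # randomly placed within the run
        off <- if (slack > 0L) sample.int(slack + 1L, 1L) - 1L else 0L
        ws <- starts[ri] + off + (seq_len(k) - 1L) * window
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = ws, end = ws + window - 1L,
          pos = ws + window %/% 2L, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    warning("no unannotated stretch can hold a window; empty anchor set")
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), pos = integer(0),
                      strand = character(0))
  }
  res
}

#' Anchor-centred metaprofile of a signal track
#'
#' @param track list of per-chromosome numeric vectors (see
#'   [track_from_bedgraph()]).
#' @param anchors data frame with `chrom`, `pos`, `strand`, and optionally
#'   `abundance` (used by the filter).
#' @param half_width profile half-extent; offsets run from `-half_width`
#'   to `+half_width`.
#' @param min_abundance anchors with `abundance` below this are excluded.
#' @return object of class `metaprofile`: data frame with `offset`,
#'   `mean`, `sem`, `n`; attributes `n_anchors` (contributing) and
#'   `n_skipped` (edge or filtered).
#' @export
metaprofile <- function(track, anchors, half_width = 500L,
                        min_abundance = -Inf) {
  if (!is.null(anchors$abundance)) {
    drop_f <- anchors$abundance < min_abundance
  } else drop_f <- rep(FALSE, nrow(anchors))
  width <- 2L * half_width + 1L
  rows <- list()
  n_skipped <- sum(drop_f)
  for (i in which(!drop_f)) {
    ch <- anchors$chrom[i]
    if (!ch %in% names(track)) { n_skipped <- n_skipped + 1L; next }
    at <- anchors$pos[i] + (-half_width):half_width
    if (at[1L] < 1L || at[width] > length(track[[ch]])) {
      n_skipped <- n_skipped + 1L
      next
    }
    v <- track[[ch]][at]
    if (!is.null(anchors$strand) && anchors$strand[i] == "-") v <- rev(v)
    rows[[length(rows) + 1L]] <- v
  }
  n <- length(rows)
  if (n == 0L) stop("no usable anchors")
  m <- do.call(rbind, rows)
  prof <- data.frame(offset = (-half_width):half_width,
                     mean = colMeans(m),
                     sem = if (n >= 2L) apply(m, 2L, stats::sd) / sqrt(n)
                     else NA_real_,
                     n = n)
  structure(prof, class = c("metaprofile", "data.frame"),
            n_anchors = n, n_skipped = n_skipped)
}

#' @export
print.metaprofile <- function(x, ...) {
  cat(sprintf("metaprofile over %d anchors (%d skipped), offsets %d..%d\n",
              attr(x, "n_anchors"), attr(x, "n_skipped"),
              min(x$offset), max(x$offset)))
  cat(sprintf("  signal range %.4g .. %.4g\n", min(x$mean), max(x$mean)))
  invisible(x)
}

#' Plot a metaprofile with its SEM band
#'
#' @param x a `metaprofile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metaprofile <- function(x, ...) {
  graphics::plot(x$offset, x$mean, type = "l", xlab = "offset (nt)",
                 ylab = "mean signal", ...)
  if (!all(is.na(x$sem))) {
    graphics::polygon(c(x$offset, rev(x$offset)),
                      c(x$mean + x$sem, rev(x$mean - x$sem)),
                      border = NA, col = grDevices::adjustcolor("grey",
                                                                0.5))
    graphics::lines(x$offset, x$mean)
  }
  invisible(x)
}

#' Top / bottom abundance-quartile metaprofiles
#'
#' @param track signal track.
#' @param anchors anchor data frame with an `abundance` column.
#' @param half_width profile half-extent.
#' @return list with `top` and `bottom` metaprofiles (1st and 4th
#'   abundance quartiles; quartile size is `floor(n/4)`, ties broken by
#'   stable anchor order).
#' @export
quartile_profiles <- function(track, anchors, half_width = 500L) {
  n <- nrow(anchors)
  if (n < 4L) stop("need at least 4 anchors for quartiles")
  if (is.null(anchors$abundance)) stop("anchors need an 'abundance' column")
  k <- n %/% 4L
  ord <- order(-anchors$abundance)   # stable: ties keep input order
  list(top = metaprofile(track, anchors[ord[seq_len(k)], ], half_width),
       bottom = metaprofile(track, anchors[ord[(n - k + 1L):n], ],
                            half_width))
}
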