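annotation_categories <- c(
  "gencode", "tfbs", "fantom5", "promoter", "enhancer", "dyadic", "dhs",
  "super-enhancer"
)

#' Generate synthetic functional-annotation tracks
#'
#' Builds `k` interval tracks over the panel's chromosome span with genome
#' coverage fractions log-spaced across `coverage_range` (real annotation
#' compendia span several orders of magnitude of coverage). Each track is a
#' set of 1-based inclusive intervals; the first interval of every track is
#' anchored on a randomly chosen variant so no track is empty of variants.
#'
#' @param panel A `genotype_panel` (only `meta` is used).
#' @param k Number of tracks; `k = 0` gives an empty set.
#' @param coverage_range `(lo, hi)` coverage fractions, `0 < lo <= hi < 1`.
#' @param mean_intervals Average number of intervals per track.
#' @param seed Top-level seed (`"annotations"` substream).
#' @return An `annotation_set` tibble with columns `track`, `category`,
#'   `chrom`, `start`, `end` (1-based inclusive) and attributes `span`
#'   (chromosome extent used for coverage fractions).
#' @export
generate_annotations <- function(panel, k, coverage_range = c(1e-4, 0.647),
                                 mean_intervals = 25, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  lo <- coverage_range[1]
  hi <- coverage_range[2]
  if (!(lo > 0 && lo <= hi && hi < 1)) {
    abort("coverage_range must satisfy 0 < lo <= hi < 1")
  }
  span_lo <- min(panel$meta$pos)
  span_hi <- max(panel$meta$pos)
  span <- span_hi - span_lo + 1
  chrom <- panel$meta$chrom[1]
  set_stream_seed(seed, "annotations")

  if (k == 0) {
    out <- tibble(track = character(), category = character(),
                  chrom = character(), start = integer(), end = integer())
    return(structure(out, span = c(span_lo, span_hi),
                     class = c("annotation_set", class(out))))
  }

  cov <- if (k == 1) hi else lo * (hi / lo)^((seq_len(k) - 1) / (k - 1))
  tracks <- purrr::imap(cov, function(cv, t) {
    total <- max(1, round(cv * span))
    n_int <- max(1L, min(mean_intervals, total))
    g <- rexp(n_int)
    lens <- pmax(1, round(total * g / sum(g)))
    # anchor the first interval on a variant; place the rest uniformly
    anchor <- sample(panel$meta$pos, 1)
    starts <- c(
      max(span_lo, anchor - lens[1] %/% 2),
      if (n_int > 1) {
        sort(sample.int(span, n_int - 1, replace = TRUE)) + span_lo - 1
      }
    )
    ends <- pmin(starts + lens - 1, span_hi)
    tibble(
      track = sprintf("track_%03d", t),
      category = annotation_categories[(t - 1) %% length(annotation_categories) + 1],
      chrom = chrom,
      start = as.integer(starts),
      end = as.integer(ends)
    )
  })
  out <- list_rbind(tracks)
  structure(out, span = c(span_lo, span_hi),
            class = c("annotation_set", class(out)))
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- cummax(end[o])
  keep <- c(TRUE, start[-1] > end[-length(end)] + 0)
  grp <- cumsum(keep)
  tibble(
    start = as.numeric(tapply(start, grp, min)),
    end = as.numeric(tapply(end, grp, max))
  )
}

#' Per-track genome coverage fractions
#'
#' Union length of each track's intervals divided by the annotated span.
#'
#' @param annotations An `annotation_set`.
#' @return Tibble with `track`, `category`, `coverage`.
#' @export
coverage_fraction <- function(annotations) {
  span <- attr(annotations, "span")
  width <- span[2] - span[1] + 1
  annotations |>
    as_tibble() |>
    group_by(.data$track, .data$category) |>
    summarise(
      coverage = {
        mi <- merge_intervals(.data$start, .data$end)
        sum(mi$end - mi$start + 1) / width
      },
      .groups = "drop"
    )
}

#' Variant-by-track annotation indicators
#'
#' Intersects variant positions with each track's intervals (1-based
#' inclusive on both sides). Entry `[i, t]` is 1 iff variant `i` falls in
#' any interval of track `t`.
#'
#' @param panel A `genotype_panel` (or its `meta` tibble).
#' @param annotations An `annotation_set`.
#' @return An integer matrix, variants x tracks, with track column names.
#' @export
annotate_variants <- function(panel, annotations) {
  meta <- if (inherits(panel, "genotype_panel")) panel$meta else panel
  ann <- as_tibble(annotations)
  tracks <- unique(ann$track)
  out <- matrix(0L, nrow(meta), length(tracks),
                dimnames = list(NULL, tracks))
  for (t in seq_along(tracks)) {
    tr <- ann[ann$track == tracks[t], ]
    if (!all(tr$chrom %in% unique(meta$chrom))) {
      abort("chromosome labels of track do not match the panel")
    }
    mi <- merge_intervals(tr$start, tr$end)
    idx <- findInterval(meta$pos, mi$start)
    hit <- idx > 0 & meta$pos <= mi$end[pmax(idx, 1)]
    out[, t] <- as.integer(hit)
  }
  out
}

#' Read and write annotation tracks as BED
#'
#' BED is 0-based half-open; intervals are converted explicitly from/to the
#' package's 1-based inclusive representation (`start_bed = start - 1`,
#' `end_bed = end`). The name column carries the track id.
#'
#' @param annotations An `annotation_set`.
#' @param path File path.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` returns an
#'   `annotation_set`.
#' @export
write_bed <- function(annotations, path) {
  bed <- as_tibble(annotations) |>
    mutate(start = .data$start - 1L) |>
    select("chrom", "start", "end", "track", "category")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param span Optional `(lo, hi)` span for coverage fractions; defaults to
#'   the interval extent.
#' @export
read_bed <- function(path, span = NULL) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "track", "category"),
    col_types = "ciicc", progress = FALSE
  )
  out <- bed |>
    mutate(start = .data$start + 1L) |>
    select("track", "category", "chrom", "start", "end")
  structure(out, span = span %||% c(min(out$start), max(out$end)),
            class = c("annotation_set", class(out)))
}
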