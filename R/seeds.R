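#' Derive a reproducible substream seed
#'
#' A single top-level seed fans out to named substreams (panel, imputation,
#' annotations, phenotype, ...) so that each component of a simulation is
#' reproducible on its own: regenerating the annotations does not perturb
#' the genotypes. The mapping is a fixed integer hash of `(seed, stream)`
#' kept below 2^31 so it is always a valid R seed.
#'
#' @param seed Integer top-level seed.
#' @param stream Character name of the substream.
#' @return An integer seed.
#' @examples
#' substream_seed(1, "panel")
#' substream_seed(1, "phenotype")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  chars <- utf8ToInt(stream)
  h <- sum(chars * seq_along(chars)) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483629)
}

set_stream_seed <- function(seed, stream) {
  if (!is.null(seed)) set.seed(substream_seed(seed, stream))
  invisible(NULL)
}
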