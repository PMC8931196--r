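#' Derive a per-stage / per-item seed from a master seed
#'
#' Deterministic counter scheme: every stage of the pipeline draws its own
#' seed as a fixed affine hash of (master seed, counter), kept below
#' 2^31 - 1 so it is always a valid R integer seed. Stages are thereby
#' independently reproducible from the master seed alone.
#'
#' @param master master seed (integer).
#' @param counter non-negative integer identifying the stage or item.
#' @return integer seed.
#' @export
seed_for <- function(master, counter) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(counter) * 7919 + 12345) %% 2147483647)
}
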