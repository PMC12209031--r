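#' Reference recording census
#'
#' The recording campaign this pipeline was designed around: 18 rats in
#' three pharmacological arms (vehicle VH, quinpirole QP, raclopride RC),
#' with 81, 80, and 78 orbitofrontal single units recorded per arm. Used
#' by the synthetic generator to pick realistic population sizes and by
#' consistency checks on the census arithmetic (total units, units per
#' rat).
#'
#' @return Data frame with columns `group` and `n_units`; the number of
#'   rats is attached as attribute `n_rats`.
#' @export
recording_census <- function() {
  structure(
    data.frame(group = c("VH", "QP", "RC"),
               n_units = c(81L, 80L, 78L),
               stringsAsFactors = FALSE),
    n_rats = 18L
  )
}
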