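#' Published slice-measurement benchmark table
#'
#' Reference comparison of 17 white-peony decoction slices: caliper-measured
#' ("actual") long/short diameters against the image pipeline's predictions,
#' with the error and accuracy percentages as printed in the published
#' comparison (one decimal). Two printed accuracy cells are internally
#' inconsistent with their own error cells: object 4 long-accuracy is
#' printed 94.3 where `100 - 5.6 = 94.4`, and object 16 long-accuracy is
#' printed 99.0 where `100 - 0.9 = 99.1`. The data are kept as printed;
#' recomputation via [error_accuracy()] yields the consistent values.
#'
#' @return Data frame with columns `object`, `long_actual`, `short_actual`,
#'   `long_pred`, `short_pred`, `area_pred`, `long_error`, `short_error`,
#'   `long_acc`, `short_acc`.
#' @export
slice_benchmark <- function() {
  path <- system.file("extdata", "slice_benchmark.csv", package = "slicemetry",
                      mustWork = TRUE)
  utils::read.csv(path)
}
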