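# Canonical dataset container layout (MAT-compatible, single file):
#   data              trials x channels x samples, double
#   fs, t0            scalars
#   subject_ids       1 x trials (registry indices)
#   conditions, stimulus_ids, modalities   char arrays, one row per trial
#   subject_labels, subject_dataset        char arrays, one row per subject
#   channel_names     char array, one row per channel
#   channel_positions channels x 3 unit-sphere coordinates
#   equiv_labels, equiv_channels           10-10 equivalence table
#   provenance        JSON-encoded char row vector

CONTAINER_REQUIRED <- c("data", "fs", "t0", "subject_ids", "conditions",
                        "stimulus_ids", "subject_labels", "channel_names",
                        "channel_positions")

#' Write an ERP dataset to the MAT-compatible container
#'
#' @param ds an `erp_dataset`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_container <- function(ds, path) {
  stopifnot(inherits(ds, "erp_dataset"))
  assert_that(all(is.finite(ds$data)), "validation_error",
              "dataset contains non-finite samples; refusing to write")
  vars <- list(
    data = ds$data,
    fs = ds$fs,
    t0 = ds$t0,
    subject_ids = as.numeric(ds$meta$subject_id),
    conditions = as.character(ds$meta$condition),
    stimulus_ids = as.character(ds$meta$stimulus_id),
    modalities = as.character(ds$meta$modality),
    subject_labels = ds$subjects$ids,
    subject_dataset = unname(ds$subjects$dataset_of),
    channel_names = ds$montage$names,
    channel_positions = ds$montage$positions3d,
    equiv_labels = names(ds$montage$equivalences),
    equiv_channels = ds$montage$names[ds$montage$equivalences],
    provenance = jsonlite::toJSON(ds$provenance, auto_unbox = TRUE,
                                  digits = NA)
  )
  write_mat(vars, path)
}

#' Read an ERP dataset from the MAT-compatible container
#'
#' Round-trips with [write_container()]: integer-valued fields exactly,
#' floating-point data to better than 1e-6 relative error (bit-exact in
#' practice, since samples are stored as doubles).
#'
#' @param path container file path.
#' @return an `erp_dataset`.
#' @export
read_container <- function(path) {
  v <- read_mat(path)
  missing <- setdiff(CONTAINER_REQUIRED, names(v))
  assert_that(length(missing) == 0, "format_error",
              "container is missing required array(s): %s",
              paste(missing, collapse = ", "))
  data <- v$data
  assert_that(length(dim(data)) == 3, "dimension_error",
              "'data' must be trials x channels x samples, got %s",
              paste(dim(data), collapse = " x "))
  n <- dim(data)[1]; nchan <- dim(data)[2]
  len_of <- function(x) if (is.character(x)) length(x) else length(as.numeric(x))
  for (f in c("subject_ids", "conditions", "stimulus_ids"))
    assert_that(len_of(v[[f]]) == n, "dimension_error",
                "'%s' has %d entries for %d trials", f, len_of(v[[f]]), n)
  assert_that(length(v$channel_names) == nchan &&
              nrow(as.matrix(v$channel_positions)) == nchan,
              "dimension_error",
              "channel tables do not match the %d data channels", nchan)
  eq <- character(0)
  if (length(v$equiv_labels %||% character(0)))
    eq <- stats::setNames(v$equiv_channels, v$equiv_labels)
  mont <- montage(v$channel_names, as.matrix(v$channel_positions), eq)
  reg <- subject_registry(v$subject_labels,
                          v$subject_dataset %||% NULL)
  modality <- if (n == 0) character(0)
    else (v$modalities %||% rep("synthetic", n))
  meta <- data.frame(
    subject_id = as.integer(v$subject_ids),
    condition = if (n == 0) character(0) else as.character(v$conditions),
    stimulus_id = if (n == 0) character(0) else as.character(v$stimulus_ids),
    modality = modality,
    stringsAsFactors = FALSE
  )
  prov <- list()
  if (length(v$provenance %||% character(0)) && nzchar(v$provenance[1]))
    prov <- jsonlite::fromJSON(v$provenance[1], simplifyVector = TRUE)
  erp_dataset(data, meta, as.numeric(v$fs), as.numeric(v$t0), mont, reg, prov)
}
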