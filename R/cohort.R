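#' Construct a patient record
#'
#' Bundles one breath measurement with the diagnostic label and the clinical
#' covariates used in the cohort baseline table. The two diagnostic classes
#' are head-and-neck squamous cell carcinoma (`"HNSCC"`, the positive class
#' throughout the package) and primary lung carcinoma (`"LUNG"`).
#'
#' @param patient_id Opaque unique identifier.
#' @param label `"HNSCC"` or `"LUNG"`.
#' @param tensor A [breath_tensor()].
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param smoking Logical; currently smoking.
#' @param fasted Logical; no food or drink intake within 4 h of measurement.
#'   `NA` encodes unknown fasting status (kept as missing, never imputed).
#' @param device_serial E-nose device identifier (five devices in the
#'   emulated study design).
#' @param tumor_stage One of `"I"`, `"II"`, `"III"`, `"IV"`, `"missing"`.
#' @param histology Free-text histology category.
#' @param subsite Tumor subsite, or `NA` when not applicable (lung cases).
#' @return A `patient_record` object.
#' @export
patient_record <- function(patient_id, label, tensor, age = NA_real_,
                           sex = NA_character_, smoking = NA,
                           fasted = NA, device_serial = NA_character_,
                           tumor_stage = "missing",
                           histology = NA_character_,
                           subsite = NA_character_) {
  label <- match.arg(label, c("HNSCC", "LUNG"))
  if (!is.na(sex)) sex <- match.arg(sex, c("M", "F"))
  tumor_stage <- match.arg(tumor_stage, c("I", "II", "III", "IV", "missing"))
  if (!inherits(tensor, "breath_tensor")) tensor <- breath_tensor(tensor)
  structure(list(
    patient_id = as.character(patient_id), label = label, tensor = tensor,
    age = as.numeric(age), sex = sex, smoking = as.logical(smoking),
    fasted = as.logical(fasted), device_serial = as.character(device_serial),
    tumor_stage = tumor_stage, histology = as.character(histology),
    subsite = as.character(subsite)), class = "patient_record")
}

#' Construct a breath cohort dataset
#'
#' @param records List of [patient_record()] objects with unique
#'   `patient_id`s.
#' @param provenance Free-text description of where the cohort came from.
#' @return A `breath_dataset` object.
#' @export
breath_dataset <- function(records = list(), provenance = "") {
  ids <- vapply(records, function(r) r$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(records) <- ids
  structure(list(records = records, provenance = as.character(provenance)[1]),
            class = "breath_dataset")
}

#' @export
length.breath_dataset <- function(x) length(x$records)

#' @export
print.breath_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<breath_dataset> %d patients (%d HNSCC, %d LUNG)\n",
              length(x), sum(labs == "HNSCC"), sum(labs == "LUNG")))
  if (nzchar(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' Diagnostic labels of a dataset, named by patient id
#' @param ds A [breath_dataset()].
#' @return Named character vector of `"HNSCC"`/`"LUNG"`.
#' @export
dataset_labels <- function(ds) {
  vapply(ds$records, function(r) r$label, character(1))
}

#' Subset a dataset by patient id
#' @param ds A [breath_dataset()].
#' @param ids Patient ids to keep (order preserved from `ds`).
#' @return A [breath_dataset()] with the selected records.
#' @export
subset_dataset <- function(ds, ids) {
  keep <- names(ds$records) %in% ids
  breath_dataset(ds$records[keep], ds$provenance)
}

meta_fields <- c("patient_id", "label", "age", "sex", "smoking", "fasted",
                 "device_serial", "tumor_stage", "histology", "subsite")

record_meta_row <- function(r) {
  data.frame(
    patient_id = r$patient_id, label = r$label, age = r$age, sex = r$sex,
    smoking = r$smoking,
    fasted = if (is.na(r$fasted)) "unknown" else if (r$fasted) "yes" else "no",
    device_serial = r$device_serial, tumor_stage = r$tumor_stage,
    histology = r$histology, subsite = r$subsite,
    temp_min = attr(r$tensor, "temperature_range")[1],
    temp_max = attr(r$tensor, "temperature_range")[2],
    stringsAsFactors = FALSE)
}

sidecar_path <- function(path) {
  sub("\\.csv$", "", path, ignore.case = TRUE) |> paste0("_meta.csv")
}

#' Write a cohort to disk
#'
#' Two on-disk encodings are supported. `csv_long` writes one measurements
#' file with columns `patient_id, temperature_step, cycle, sensor, value`
#' (1-based contiguous indices) plus a metadata sidecar `<path>_meta.csv`
#' with one row per patient; unknown fasting status is written as
#' `"unknown"`. `json` writes a single document with the tensor nested as
#' `[temperature][cycle][sensor]` arrays. Tensor values are written at full
#' double precision so a read-back reproduces the dataset exactly.
#'
#' @param ds A [breath_dataset()].
#' @param path Output file path (for `csv_long`, the measurements file; the
#'   sidecar path is derived from it).
#' @param format `"csv_long"` or `"json"`.
#' @return Invisibly, `path`.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(ds, path, format = c("csv_long", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "breath_dataset"))
  if (format == "json") {
    doc <- list(
      provenance = ds$provenance,
      patients = lapply(unname(ds$records), function(r) {
        m <- as.list(record_meta_row(r))
        m$fasted <- NULL
        c(m[setdiff(names(m), c("temp_min", "temp_max"))],
          list(fasted = if (is.na(r$fasted)) "unknown" else
                        if (r$fasted) "yes" else "no",
               temperature_range = attr(r$tensor, "temperature_range"),
               tensor = unclass(r$tensor)))
      }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = FALSE)
    return(invisible(path))
  }
  dims <- tensor_dims()
  rows <- lapply(unname(ds$records), function(r) {
    data.frame(patient_id = r$patient_id,
               temperature_step = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
               cycle = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
               sensor = rep(seq_len(dims[3]), each = dims[1] * dims[2]),
               value = sprintf("%.17g", as.numeric(r$tensor)),
               stringsAsFactors = FALSE)
  })
  long <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), temperature_step = integer(0),
               cycle = integer(0), sensor = integer(0), value = character(0))
  data.table::fwrite(long, path)
  meta <- if (length(ds$records))
    do.call(rbind, lapply(unname(ds$records), record_meta_row)) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 12)),
                    c(meta_fields, "temp_min", "temp_max"))
  meta$provenance <- rep(ds$provenance, nrow(meta))
  data.table::fwrite(meta, sidecar_path(path))
  invisible(path)
}

parse_fasted <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("yes", "TRUE", "true")] <- TRUE
  out[x %in% c("no", "FALSE", "false")] <- FALSE
  out
}

build_tensor_checked <- function(pid, t_idx, c_idx, s_idx, value,
                                 temperature_range) {
  dims <- tensor_dims()
  ok_idx <- t_idx >= 1 & t_idx <= dims[1] & c_idx >= 1 & c_idx <= dims[2] &
    s_idx >= 1 & s_idx <= dims[3]
  if (!all(ok_idx)) {
    j <- which(!ok_idx)[1]
    stop(sprintf("patient %s: index out of range at (temperature=%s, cycle=%s, sensor=%s)",
                 pid, t_idx[j], c_idx[j], s_idx[j]), call. = FALSE)
  }
  arr <- array(NA_real_, dims)
  lin <- cbind(t_idx, c_idx, s_idx)
  if (anyDuplicated(lin)) {
    j <- which(duplicated(lin))[1]
    stop(sprintf("patient %s: duplicate cell (temperature=%d, cycle=%d, sensor=%d)",
                 pid, t_idx[j], c_idx[j], s_idx[j]), call. = FALSE)
  }
  arr[lin] <- value
  miss <- which(is.na(arr))
  if (length(miss)) {
    ix <- arrayInd(miss[1], dims)
    stop(sprintf(
      "patient %s: tensor not fully populated, missing cell (temperature=%d, cycle=%d, sensor=%d)%s",
      pid, ix[1], ix[2], ix[3],
      if (length(miss) > 1) sprintf(" and %d more", length(miss) - 1) else ""),
      call. = FALSE)
  }
  if (any(arr <= 0)) {
    ix <- arrayInd(which(arr <= 0)[1], dims)
    stop(sprintf("patient %s: non-positive conductivity at (temperature=%d, cycle=%d, sensor=%d)",
                 pid, ix[1], ix[2], ix[3]), call. = FALSE)
  }
  breath_tensor(arr, temperature_range)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_dataset()]. The reader validates every tensor: a
#' missing or duplicated cell, an out-of-range index, a non-positive
#' conductivity or a duplicate patient id is a hard error naming the patient
#' and index. Row order in the `csv_long` measurements file is irrelevant.
#'
#' @param path File path (for `csv_long`, the measurements file written by
#'   [write_dataset()]; its `_meta.csv` sidecar must sit next to it).
#' @param format `"csv_long"` or `"json"`.
#' @return A [breath_dataset()].
#' @export
read_dataset <- function(path, format = c("csv_long", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    recs <- lapply(doc$patients, function(p) {
      # jsonlite simplifies the [temperature][cycle][sensor] nesting straight
      # back to a 32x36x3 array in the native layout
      arr <- p$tensor
      patient_record(p$patient_id, p$label,
                     breath_tensor(arr, as.numeric(p$temperature_range)),
                     age = p$age %||% NA_real_, sex = p$sex %||% NA_character_,
                     smoking = p$smoking %||% NA,
                     fasted = parse_fasted(p$fasted %||% "unknown"),
                     device_serial = p$device_serial %||% NA_character_,
                     tumor_stage = p$tumor_stage %||% "missing",
                     histology = p$histology %||% NA_character_,
                     subsite = p$subsite %||% NA_character_)
    })
    return(breath_dataset(recs, doc$provenance %||% ""))
  }
  mpath <- sidecar_path(path)
  if (!file.exists(mpath)) stop("metadata sidecar not found: ", mpath, call. = FALSE)
  long <- data.table::fread(path, colClasses = list(
    character = "patient_id", numeric = "value"))
  meta <- data.table::fread(mpath, colClasses = list(character = c(
    "patient_id", "label", "sex", "fasted", "device_serial", "tumor_stage",
    "histology", "subsite")))
  if (anyDuplicated(meta$patient_id)) {
    stop("duplicate patient_id in metadata: ",
         paste(unique(meta$patient_id[duplicated(meta$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(unique(long$patient_id), meta$patient_id)
  if (length(extra)) {
    stop("measurements for patients absent from metadata: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  blank2na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    for (f in c("sex", "device_serial", "histology", "subsite")) {
      m[[f]] <- blank2na(m[[f]])
    }
    rows <- long[long$patient_id == m$patient_id, ]
    if (!nrow(rows)) {
      stop(sprintf("patient %s: no measurement rows", m$patient_id),
           call. = FALSE)
    }
    tens <- build_tensor_checked(m$patient_id, rows$temperature_step,
                                 rows$cycle, rows$sensor, rows$value,
                                 c(m$temp_min, m$temp_max))
    patient_record(m$patient_id, m$label, tens, age = m$age, sex = m$sex,
                   smoking = m$smoking, fasted = parse_fasted(m$fasted),
                   device_serial = m$device_serial,
                   tumor_stage = m$tumor_stage, histology = m$histology,
                   subsite = m$subsite)
  })
  prov <- if ("provenance" %in% names(meta) && nrow(meta)) meta$provenance[1] else ""
  breath_dataset(recs, prov)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
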