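#' Write an expression time course as a wide TSV
#'
#' One row per gene; columns `gene_id` then one per sample named
#' `{condition}_{time}` (e.g. `UIC_2.5`).
#'
#' @param dataset Long tibble (`gene_id`, `condition`, `time`, `tpm`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm_table <- function(dataset, path) {
  check_dataset(dataset)
  wide <- dataset %>%
    dplyr::mutate(sample = paste0(.data$condition, "_", .data$time)) %>%
    dplyr::select("gene_id", "sample", "tpm") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "tpm")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide TSV expression time course
#'
#' Parses the `{condition}_{time}` sample columns back into a long tibble
#' and enforces the dataset contract: non-negative abundances, no duplicate
#' genes, and a shared time grid between conditions.
#'
#' @param path TSV path as written by [write_tpm_table()].
#' @param library_type Optional label stored as an attribute.
#' @return Long tibble (`gene_id`, `condition`, `time`, `tpm`).
#' @export
read_tpm_table <- function(path, library_type = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (!"gene_id" %in% names(raw)) abort("Missing `gene_id` column.")
  samples <- setdiff(names(raw), "gene_id")
  parsed <- regmatches(samples, regexec("^(UIC|MO)_([0-9.]+)$", samples))
  bad <- vapply(parsed, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf("Sample column '%s' is not of the form {condition}_{time}.",
                  samples[which(bad)[1]]))
  }
  if (anyDuplicated(raw$gene_id)) {
    abort(sprintf("Duplicate gene_id '%s'.",
                  raw$gene_id[anyDuplicated(raw$gene_id)]))
  }
  long <- tidyr::pivot_longer(as_tibble(raw), -"gene_id",
                              names_to = "sample", values_to = "tpm_chr") %>%
    tidyr::separate("sample", into = c("condition", "time"), sep = "_") %>%
    dplyr::mutate(time = as.numeric(.data$time),
                  tpm = suppressWarnings(as.numeric(.data$tpm_chr)))
  if (anyNA(long$tpm)) {
    i <- which(is.na(long$tpm))[1]
    abort(sprintf("Non-numeric TPM for gene %s, sample %s_%s.",
                  long$gene_id[i], long$condition[i], long$time[i]))
  }
  if (any(long$tpm < 0)) {
    i <- which(long$tpm < 0)[1]
    abort(sprintf("Negative TPM for gene %s, sample %s_%s.",
                  long$gene_id[i], long$condition[i], long$time[i]))
  }
  out <- dplyr::select(long, "gene_id", "condition", "time", "tpm")
  attr(out, "library_type") <- library_type
  check_dataset(out)
}

#' Per-gene maximum abundance
#'
#' `m_i`: each gene's maximum abundance over both conditions and all
#' timepoints, the gene-level scale used by the variance-stabilizing
#' transform.
#'
#' @param dataset Long tibble (`gene_id`, `condition`, `time`, `tpm`).
#' @return Tibble `gene_id`, `m`.
#' @export
gene_max <- function(dataset) {
  check_dataset(dataset)
  dataset %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(m = max(.data$tpm), .groups = "drop")
}

#' Apply a per-gene multiplicative abundance correction
#'
#' Multiplies every abundance of a gene by its correction factor (e.g. a
#' composition-bias correction supplied upstream); the identity is the
#' default. Gene maxima change accordingly.
#'
#' @param dataset Long tibble (`gene_id`, `condition`, `time`, `tpm`).
#' @param correction Either `NULL` (identity) or a tibble `gene_id`,
#'   `factor` covering every gene in `dataset`.
#' @return Corrected dataset.
#' @export
correct_abundance <- function(dataset, correction = NULL) {
  check_dataset(dataset)
  if (is.null(correction)) return(dataset)
  if (!all(c("gene_id", "factor") %in% names(correction))) {
    abort("`correction` needs columns gene_id and factor.")
  }
  missing <- setdiff(unique(dataset$gene_id), correction$gene_id)
  if (length(missing)) {
    abort(sprintf("Correction table missing gene(s): %s.",
                  paste(utils::head(missing, 3), collapse = ", ")))
  }
  lib <- attr(dataset, "library_type")
  out <- dataset %>%
    dplyr::left_join(correction, by = "gene_id") %>%
    dplyr::mutate(tpm = .data$tpm * .data$factor) %>%
    dplyr::select("gene_id", "condition", "time", "tpm")
  attr(out, "library_type") <- lib
  out
}

# longest run of TRUE in a logical vector
longest_run <- function(x) {
  if (!length(x)) return(0L)
  r <- rle(x)
  runs <- r$lengths[r$values]
  if (length(runs)) max(runs) else 0L
}

#' Filter genes with sustained temporal expression
#'
#' A gene passes when, in every supplied library type, at least one
#' condition's time series contains a run of `run_len` consecutive
#' timepoints with uncorrected TPM strictly greater than `min_tpm`
#' (default: six consecutive samples above 0.4). With
#' `mode = "pooled"` the run is instead sought in the interleaved
#' UIC/MO sample sequence ordered by time.
#'
#' @param datasets A single long tibble or a list of them (one per library
#'   type; all sharing the gene universe).
#' @param min_tpm Strict lower TPM bound (default 0.4).
#' @param run_len Required run length (default 6).
#' @param mode `"per_condition"` (default) or `"pooled"`.
#' @return Sorted character vector of passing gene ids.
#' @export
filter_expressed <- function(datasets, min_tpm = 0.4, run_len = 6,
                             mode = c("per_condition", "pooled")) {
  mode <- match.arg(mode)
  if (is.data.frame(datasets)) datasets <- list(datasets)
  purrr::walk(datasets, check_dataset)
  universe <- sort(unique(datasets[[1]]$gene_id))
  for (ds in datasets) {
    if (!setequal(unique(ds$gene_id), universe)) {
      abort("All library types must share the gene universe.")
    }
    if (run_len > length(unique(ds$time))) {
      abort("`run_len` exceeds the number of timepoints.")
    }
  }
  pass_one <- function(ds) {
    if (mode == "per_condition") {
      ds %>%
        dplyr::arrange(.data$gene_id, .data$condition, .data$time) %>%
        dplyr::group_by(.data$gene_id, .data$condition) %>%
        dplyr::summarise(run = longest_run(.data$tpm > min_tpm),
                         .groups = "drop") %>%
        dplyr::group_by(.data$gene_id) %>%
        dplyr::summarise(pass = max(.data$run) >= run_len, .groups = "drop")
    } else {
      ds %>%
        dplyr::arrange(.data$gene_id, .data$time, .data$condition) %>%
        dplyr::group_by(.data$gene_id) %>%
        dplyr::summarise(pass = longest_run(.data$tpm > min_tpm) >= run_len,
                         .groups = "drop")
    }
  }
  passes <- purrr::map(datasets, pass_one)
  ok <- purrr::reduce(passes, function(a, b) {
    dplyr::inner_join(a, b, by = "gene_id") %>%
      dplyr::transmute(gene_id = .data$gene_id,
                       pass = .data$pass.x & .data$pass.y)
  })
  sort(ok$gene_id[ok$pass])
}
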