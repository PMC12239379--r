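#' Read a methylation matrix from TSV
#'
#' Expects a tab-separated file whose first column holds probe ids and whose
#' header holds sample ids; all other cells are numeric or the literal token
#' `NA`. Coordinates throughout the package are 1-based inclusive (array
#' annotation convention); conversion to BED's 0-based half-open scheme
#' happens only in [write_annotation_bed()].
#'
#' @param path File path.
#' @param scale Declared value scale, `"beta"` or `"M"` (stored as an
#'   attribute; beta values are range-checked).
#' @return Numeric matrix (probes x samples) with a `scale` attribute.
#' @export
read_meth_matrix <- function(path, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs an id column plus data", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate probe id(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
         call. = FALSE)
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample column(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col) || is.factor(col)) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(is.na(num) & !is.na(col) & as.character(col) != "NA")
      if (length(bad) > 0) {
        stop("non-numeric value at row ", bad[1], ", column '", samples[j],
             "': '", col[bad[1]], "'", call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (scale == "beta") {
    rng <- range(mat, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("beta-scale matrix has values outside [0, 1]", call. = FALSE)
    }
  }
  attr(mat, "scale") <- scale
  mat
}

#' @rdname read_meth_matrix
#' @param mat Probes x samples matrix with rownames and colnames.
#' @export
write_meth_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  # %.17g keeps doubles exact through the text round-trip
  fm <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  fm[is.na(mat)] <- "NA"
  df <- data.frame(probe_id = rownames(mat), fm, stringsAsFactors = FALSE)
  names(df) <- c("probe_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read or write a sample sheet (CSV)
#'
#' The sample sheet carries one row per sample with subject id, timepoint
#' (`T0`, `T14`, `T90`), age, sex (`M`/`F`), plate batch, collection date,
#' BMI and smoking flag. `(subject_id, timepoint)` must be unique.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(validate_sample_sheet(sheet), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(df) {
  req <- c("sample_id", "subject_id", "timepoint")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_tp <- setdiff(unique(df$timepoint), c("T0", "T14", "T90"))
  if (length(bad_tp) > 0) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$subject_id, df$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, timepoint) pair: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  if ("collection_date" %in% names(df) && is.character(df$collection_date)) {
    df$collection_date <- as.Date(df$collection_date)
  }
  tibble::as_tibble(df)
}

#' Read a SNP dosage matrix
#'
#' Two dialects behind one contract: a TSV with columns `snp_id`,
#' `chromosome`, `position`, then one dosage column per subject (values in
#' `[0, 2]`, `NA` allowed); or a minimal VCF subset (CHROM, POS, ID, GT
#' genotypes) where `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2` and `./.` is missing.
#' Out-of-range dosages are an error, never silently clipped.
#'
#' @param path File path; a `.vcf` extension or a leading `##fileformat=VCF`
#'   line selects the VCF dialect.
#' @return List with `dosages` (SNPs x subjects matrix) and `snps` (tibble:
#'   `snp_id`, `chromosome`, `position`).
#' @export
read_dosages <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\\.vcf$", path, ignore.case = TRUE) ||
      startsWith(first, "##fileformat=VCF")) {
    return(read_dosages_vcf(path))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("snp_id", "chromosome", "position")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("dosage file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$snp_id)) {
    stop("duplicate snp_id: ", df$snp_id[duplicated(df$snp_id)][1],
         call. = FALSE)
  }
  dose <- as.matrix(df[, setdiff(names(df), req), drop = FALSE])
  storage.mode(dose) <- "double"
  rownames(dose) <- df$snp_id
  rng <- range(dose, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosage outside [0, 2]: ", if (rng[2] > 2) rng[2] else rng[1],
         call. = FALSE)
  }
  list(dosages = dose,
       snps = tibble::tibble(snp_id = df$snp_id,
                             chromosome = as.character(df$chromosome),
                             position = as.integer(df$position)))
}

read_dosages_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  fixed <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT")
  subjects <- setdiff(header, fixed)
  body <- strsplit(lines[-1], "\t")
  gt_to_dose <- function(gt) {
    gt <- sub(":.*", "", gt)
    alleles <- strsplit(gt, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(as.numeric(alleles))
  }
  rows <- lapply(body, function(f) {
    names(f) <- header[seq_along(f)]
    d <- vapply(f[subjects], gt_to_dose, numeric(1))
    list(id = f[["ID"]], chrom = f[["CHROM"]], pos = as.integer(f[["POS"]]),
         dose = d)
  })
  ids <- vapply(rows, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate snp_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  dose <- do.call(rbind, lapply(rows, `[[`, "dose"))
  rownames(dose) <- ids
  colnames(dose) <- subjects
  list(dosages = dose,
       snps = tibble::tibble(
         snp_id = ids,
         chromosome = vapply(rows, `[[`, character(1), "chrom"),
         position = vapply(rows, function(r) r$pos, integer(1))))
}

#' Export probe annotation as BED
#'
#' Converts the package's 1-based inclusive positions to BED's 0-based
#' half-open intervals at this boundary only.
#'
#' @param annotation Tibble with `probe_id`, `chromosome`, `position`.
#' @param path Output path.
#' @export
write_annotation_bed <- function(annotation, path) {
  stopifnot(all(c("probe_id", "chromosome", "position") %in% names(annotation)))
  bed <- data.frame(chrom = annotation$chromosome,
                    start = annotation$position - 1L,
                    end = annotation$position,
                    name = annotation$probe_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an association result table
#'
#' Fixed column order `feature, estimate, se, stat, p, q` (extra columns
#' appended after), tab-separated, full precision.
#'
#' @param results Result tibble (e.g. from [fit_mixed_ewas()]).
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  lead <- intersect(c("feature", "probe_id", "estimate", "se", "stat", "p", "q"),
                    names(results))
  df <- as.data.frame(results)[, c(lead, setdiff(names(results), lead)),
                               drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Load and validate a run configuration (YAML)
#'
#' Unknown keys are rejected (with a nearest-known-key suggestion) and
#' defaults are filled for absent optional keys.
#'
#' @param path YAML file path.
#' @param defaults Named list of known keys and their defaults; keys whose
#'   default is the sentinel `"__required__"` must be present.
#' @return Named list: defaults overridden by the file's values.
#' @export
load_run_config <- function(path, defaults = cohort_config_defaults()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    key <- unknown[1]
    dists <- utils::adist(key, names(defaults))
    hint <- names(defaults)[which.min(dists)]
    stop("unknown config key '", key, "'; did you mean '", hint, "'?",
         call. = FALSE)
  }
  required <- names(defaults)[vapply(defaults, identical, logical(1),
                                     "__required__")]
  missing_req <- setdiff(required, names(cfg))
  if (length(missing_req) > 0) {
    stop("missing required config key(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(defaults, cfg)
}

#' Stamp run metadata for reproducibility logging
#'
#' @param seed Integer seed used for the run.
#' @param params Named list of thresholds/settings worth recording.
#' @param files Character vector of input file paths to hash (md5 of
#'   contents via [tools::md5sum()]).
#' @return One-row tibble: timestamp, package version, seed, JSON-encoded
#'   params, and `file=hash` pairs.
#' @export
run_metadata <- function(seed, params = list(), files = character(0)) {
  hashes <- if (length(files) > 0) {
    paste(basename(files), unname(tools::md5sum(files)), sep = "=",
          collapse = ";")
  } else {
    ""
  }
  tibble::tibble(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("bcgmeth")),
    seed = as.integer(seed),
    params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
    input_hashes = hashes
  )
}
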