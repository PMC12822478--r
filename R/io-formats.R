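#' @title Tabular readers/writers with strict validation
#' @description All pipeline inputs are plain tab-delimited text: omics
#'   matrices (features x samples), the clinical table, GMT gene sets, the
#'   kinase-substrate map, rMATS-style AS event tables and phosphosite
#'   annotations. Loaders validate aggressively and never silently drop
#'   rows; writers round-trip matrices bit-exactly (15 significant digits).
#' @name io-formats
NULL

OMICS_LAYERS <- c("cnv", "mrna", "protein", "phosphosite")
TISSUE_CODES <- c("N", "T", "LM")
AS_EVENT_TYPES <- c("A3SS", "A5SS", "MXE", "RI", "SE")

#' Construct an omics matrix
#'
#' One omics layer as a features x samples numeric matrix on log2 scale
#' (cnv: gene-level relative copy values). Missing values are `NA`; zeros
#' are data, never missing.
#'
#' @param values Numeric matrix with feature rownames and sample colnames.
#' @param layer One of `"cnv"`, `"mrna"`, `"protein"`, `"phosphosite"`.
#'   Phosphosite feature ids follow the `GENE_[STY]position` grammar
#'   (e.g. `NDRG1_S330`).
#' @param is_normalized Has per-sample median normalization been applied?
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, layer, is_normalized = FALSE) {
  layer <- match.arg(layer, OMICS_LAYERS)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("omics matrix needs feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop("duplicate feature id: ", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop("duplicate sample id: ", dup)
  }
  if (any(is.infinite(values))) stop("omics matrix contains infinite values")
  if (layer == "phosphosite") {
    bad <- rownames(values)[!grepl("^[^_]+.*_[STY][0-9]+$", rownames(values))]
    if (length(bad)) {
      stop("phosphosite ids must follow GENE_[STY]position; offending id: ", bad[1])
    }
  }
  structure(
    list(values = values, layer = layer, is_normalized = isTRUE(is_normalized)),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> layer=%s  %d features x %d samples  (%.1f%% missing%s)\n",
    x$layer, nrow(x$values), ncol(x$values),
    100 * mean(is.na(x$values)),
    if (x$is_normalized) ", normalized" else ""
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature ids of an omics matrix
#' @param m An `omics_matrix`.
#' @export
feature_ids <- function(m) rownames(m$values)

#' Sample ids of an omics matrix
#' @param m An `omics_matrix`.
#' @export
sample_ids <- function(m) colnames(m$values)

#' Subset an omics matrix by features and/or samples
#' @param m An `omics_matrix`.
#' @param features,samples Character vectors of ids to keep (NULL = all).
#' @export
subset_omics <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing)) stop("unknown feature ids: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing)) stop("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  omics_matrix(v, m$layer, m$is_normalized)
}

#' Map phosphosite ids to parent gene symbols
#' @param site_ids Character vector of `GENE_[STY]pos` ids.
#' @return Character vector of gene symbols.
#' @export
site_to_gene <- function(site_ids) sub("_[STY][0-9]+$", "", site_ids)

#' Read an omics matrix from TSV
#'
#' First column = feature ids, header row = sample ids; empty cells or
#' "NA"/"na" are missing. A leading `#scale=log2` comment line marks a
#' normalized matrix. Ragged rows, duplicate ids and non-numeric cells are
#' parse errors naming the offending line.
#'
#' @param path File path.
#' @param layer Omics layer (see [omics_matrix()]).
#' @return A validated `omics_matrix`.
#' @export
load_omics_matrix <- function(path, layer) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_normalized <- FALSE
  line_offset <- 0L
  while (length(lines) && startsWith(lines[1], "#")) {
    if (grepl("^#scale=log2", lines[1])) is_normalized <- TRUE
    lines <- lines[-1]
    line_offset <- line_offset + 1L
  }
  if (length(lines) < 2) stop("matrix file needs a header and at least one feature row: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n_col <- length(header)
  sample_ids <- header[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  feats <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L)
  # field counts from tab counts: trailing empty cells keep their tabs even
  # though strsplit drops them, so raggedness stays detectable
  n_fields <- nchar(lines[-1]) - nchar(gsub("\t", "", lines[-1], fixed = TRUE)) + 1L
  for (i in seq_along(body)) {
    row <- body[[i]]
    lineno <- i + 1L + line_offset
    if (n_fields[i] != n_col) {
      stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                   lineno, path, n_fields[i], n_col))
    }
    if (length(row) < n_col) row <- c(row, rep("", n_col - length(row)))
    feats[i] <- row[1]
    cells <- row[-1]
    miss <- cells == "" | toupper(cells) == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at line %d, column %s of %s",
                   cells[bad[1]], lineno, sample_ids[bad[1]], path))
    }
    num[miss] <- NA_real_
    vals[i, ] <- num
  }
  if (anyDuplicated(feats)) {
    dup <- feats[duplicated(feats)][1]
    stop("duplicate feature id '", dup, "' in ", path)
  }
  rownames(vals) <- feats
  colnames(vals) <- sample_ids
  message(sprintf("loaded %d features x %d samples from %s", nrow(vals), ncol(vals), path))
  omics_matrix(vals, layer, is_normalized)
}

#' Write an omics matrix to TSV
#'
#' Values are serialized with 15 significant digits so a write/read round
#' trip reproduces the matrix bit-exactly. Normalized matrices get a
#' `#scale=log2` header comment.
#'
#' @param m An `omics_matrix`.
#' @param path Output path.
#' @export
write_omics_matrix <- function(m, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (m$is_normalized) writeLines("#scale=log2", con)
  writeLines(paste(c("feature_id", colnames(m$values)), collapse = "\t"), con)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)  # 17 significant digits: doubles round-trip exactly
    out[is.na(v)] <- "NA"
    out
  }
  body <- vapply(seq_len(nrow(m$values)), function(i) {
    paste(c(rownames(m$values)[i], fmt(m$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' `name TAB description TAB member...` per line; descriptions are
#' retained as an attribute. Lines with fewer than three fields, empty
#' member lists and duplicate set names are errors.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with a `descriptions` attribute.
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d fields; need name, description and >= 1 member",
                   i, length(fields)))
    }
    nms[i] <- fields[1]
    desc[i] <- fields[2]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene set name: ", nms[duplicated(nms)][1])
  }
  names(sets) <- nms
  names(desc) <- nms
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read the clinical table
#'
#' Required columns: `patient_id`, `sample_id`, `tissue` (N/T/LM),
#' `os_time` (days), `os_event` (0/1). Optional: `subtype` (C1/C2), `crs`
#' (integer 0-5), `pfs_time`, `pfs_event`.
#'
#' @param path TSV path.
#' @return A validated data frame, one row per sample.
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_clinical(df)
}

#' Validate a clinical data frame
#' @param df Data frame with the columns documented in [load_clinical()].
#' @return The validated data frame (tissue as a factor N/T/LM).
#' @export
validate_clinical <- function(df) {
  required <- c("patient_id", "sample_id", "tissue", "os_time", "os_event")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("clinical table missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  }
  bad_tissue <- setdiff(unique(df$tissue), TISSUE_CODES)
  if (length(bad_tissue)) stop("unknown tissue code: ", bad_tissue[1])
  if (any(is.na(df$os_time)) || any(is.na(df$os_event))) {
    stop("os_time and os_event must be present for every sample")
  }
  if (any(df$os_time < 0)) stop("negative os_time")
  if (!all(df$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  if ("crs" %in% names(df)) {
    ok <- is.na(df$crs) | (df$crs %in% 0:5)
    if (!all(ok)) stop("crs must be an integer in 0..5")
  }
  if ("subtype" %in% names(df)) {
    ok <- is.na(df$subtype) | df$subtype %in% c("C1", "C2")
    if (!all(ok)) stop("subtype must be C1 or C2")
  }
  if ("pfs_time" %in% names(df) && any(df$pfs_time < 0, na.rm = TRUE)) stop("negative pfs_time")
  df$tissue <- factor(df$tissue, levels = TISSUE_CODES)
  df
}

#' Write the clinical table
#' @param df Clinical data frame.
#' @param path Output path.
#' @export
write_clinical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinase-substrate map
#'
#' Two-column TSV `kinase TAB substrate` (one phosphosite per row, header
#' required) or the equivalent with extra annotation columns ignored.
#'
#' @param path TSV path.
#' @return Named list: kinase -> character vector of phosphosite ids.
#' @export
load_kinase_substrate_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("kinase", "substrate")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("kinase-substrate map missing columns: ", paste(missing, collapse = ", "))
  bad <- df$substrate[!grepl("^[^_]+.*_[STY][0-9]+$", df$substrate)]
  if (length(bad)) stop("invalid phosphosite id in map: ", bad[1])
  map <- split(df$substrate, df$kinase)
  map <- lapply(map, unique)
  if (any(lengths(map) == 0)) stop("kinase with empty substrate set")
  map
}

#' Write a kinase-substrate map
#' @param map Named list kinase -> phosphosite ids.
#' @param path Output path.
#' @export
write_kinase_substrate_map <- function(map, path) {
  df <- data.frame(
    kinase = rep(names(map), lengths(map)),
    substrate = unlist(map, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an rMATS-style alternative-splicing event table
#'
#' Expected columns: `event_id`, `gene`, `event_type` (A3SS/A5SS/MXE/RI/SE),
#' `inc_level_difference` in \[-1, 1\], `fdr` in \[0, 1\], plus one
#' `psi.<sample_id>` column per sample with PSI in \[0, 1\] (missing
#' allowed).
#'
#' @param path TSV path.
#' @return An `as_event_table`: list with `events` (data frame) and `psi`
#'   (events x samples matrix).
#' @export
load_as_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_event_table(df)
}

#' Construct/validate an AS event table from a flat data frame
#' @param df Data frame in the schema of [load_as_events()].
#' @return An `as_event_table` object.
#' @export
as_event_table <- function(df) {
  required <- c("event_id", "gene", "event_type", "inc_level_difference", "fdr")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("AS event table missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$event_id)) {
    stop("duplicate AS event id: ", df$event_id[duplicated(df$event_id)][1])
  }
  bad_type <- setdiff(unique(df$event_type), AS_EVENT_TYPES)
  if (length(bad_type)) stop("unknown AS event type: ", bad_type[1])
  if (any(abs(df$inc_level_difference) > 1, na.rm = TRUE)) {
    stop("inc_level_difference must lie in [-1, 1]")
  }
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) stop("fdr must lie in [0, 1]")
  psi_cols <- grep("^psi\\.", names(df), value = TRUE)
  psi <- as.matrix(df[, psi_cols, drop = FALSE])
  colnames(psi) <- sub("^psi\\.", "", psi_cols)
  rownames(psi) <- df$event_id
  if (any(psi < 0 | psi > 1, na.rm = TRUE)) stop("PSI values must lie in [0, 1]")
  structure(
    list(events = df[, required], psi = psi),
    class = "as_event_table"
  )
}

#' @export
print.as_event_table <- function(x, ...) {
  cat(sprintf("<as_event_table> %d events x %d samples\n",
              nrow(x$events), ncol(x$psi)))
  invisible(x)
}

#' Write an AS event table
#' @param tbl An `as_event_table`.
#' @param path Output path.
#' @export
write_as_events <- function(tbl, path) {
  psi <- as.data.frame(tbl$psi)
  names(psi) <- paste0("psi.", names(psi))
  out <- cbind(tbl$events, psi)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phosphosite functional annotations
#'
#' Columns: `site_id`, `functional_score` in \[0, 1\], `localization_class`
#' (I/II). The localization class is consumed as given, never computed.
#'
#' @param path TSV path.
#' @return Data frame keyed by `site_id`.
#' @export
load_site_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("site_id", "functional_score", "localization_class")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("site annotation missing columns: ", paste(missing, collapse = ", "))
  if (any(df$functional_score < 0 | df$functional_score > 1, na.rm = TRUE)) {
    stop("functional_score must lie in [0, 1]")
  }
  bad <- setdiff(unique(df$localization_class), c("I", "II"))
  if (length(bad)) stop("localization_class must be I or II; got ", bad[1])
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in annotation")
  df
}

#' Write phosphosite annotations
#' @param df Annotation data frame.
#' @param path Output path.
#' @export
write_site_annotation <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic results table as TSV
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
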