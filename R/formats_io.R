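# File readers/writers and the package-wide coordinate convention.
#
# Every interval in memory is 0-based, half-open [start, end), matching BED.
# Vendor probe manifests give 1-based positions; those are shifted exactly
# once, at read time. Probes are single-base points (the cytosine), strand is
# ignored throughout.

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open `[start, end)`. This is the internal
#' convention for every region type in the package (TF peaks, chromatin-state
#' segments, RNAPII-interaction regions).
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, exclusive end; must satisfy `end > start`.
#' @param label Optional character vector of labels (e.g. peak name or
#'   chromatin-state name).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_) {
  iv <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv, where = "intervals") {
  if (!all(c("chrom", "start", "end") %in% names(iv)))
    stop(where, ": columns chrom, start, end are required")
  if (any(is.na(iv$chrom) | !nzchar(iv$chrom)))
    stop(where, ": empty chromosome name")
  bad <- which(!is.finite(iv$start) | !is.finite(iv$end) |
                 iv$start < 0 | iv$start >= iv$end)
  if (length(bad))
    stop(where, ": invalid interval(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (need 0 <= start < end)")
  invisible(iv)
}

# Point-in-interval membership under the half-open convention:
# pos is inside [start, end) iff start <= pos < end.
point_in_intervals <- function(chrom, pos, intervals) {
  stopifnot(length(chrom) == length(pos))
  hit <- logical(length(pos))
  if (!length(pos) || !nrow(intervals)) return(hit)
  for (ch in unique(intervals$chrom)) {
    qi <- which(chrom == ch)
    if (!length(qi)) next
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    subj <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    qry <- IRanges::IRanges(start = pos[qi] + 1L, width = 1L)
    hit[qi] <- IRanges::countOverlaps(qry, subj) > 0L
  }
  hit
}

# Label of the (unique, validated non-overlapping) interval containing each
# point; NA where no interval contains it.
point_interval_label <- function(chrom, pos, intervals) {
  out <- rep(NA_character_, length(pos))
  if (!length(pos) || !nrow(intervals)) return(out)
  for (ch in unique(intervals$chrom)) {
    qi <- which(chrom == ch)
    if (!length(qi)) next
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    subj <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    qry <- IRanges::IRanges(start = pos[qi] + 1L, width = 1L)
    first <- IRanges::findOverlaps(qry, subj, select = "first")
    out[qi] <- ifelse(is.na(first), NA_character_, sub$label[first])
  }
  out
}

# Documented alias table for island-relation annotations. Vendor manifests
# leave the field blank for probes outside any island neighbourhood.
ISLAND_CATEGORIES <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                       "OpenSea")

island_relation_aliases <- stats::setNames(
  c("OpenSea", "OpenSea", "OpenSea", "OpenSea", "OpenSea",
    "Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf"),
  c("", "OpenSea", "Open_Sea", "open_sea", "None",
    "Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf"))

#' Read a CpG probe manifest
#'
#' Expects a tab-separated file with header columns `probe_id`, `chrom`,
#' `pos`, `island_relation` and optionally `gene_symbols` and `region_flags`
#' (both `;`-separated lists). Positions in the file are 1-based, as in
#' vendor array manifests, and are converted once to the package's 0-based
#' convention. Unknown island-relation strings are resolved through a
#' documented alias table; an empty field means `OpenSea`.
#'
#' @param path Path to the manifest TSV.
#' @return A `data.frame` of class `ProbeManifest` with columns `probe_id`,
#'   `chrom`, `pos` (0-based), `island_relation`, `gene_symbols` (list
#'   column), `region_flags` (list column).
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  required <- c("probe_id", "chrom", "pos", "island_relation")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("probe manifest ", path, ": missing mandatory column ",
         paste(miss, collapse = ", "))
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    stop("duplicate probe_id ", paste(unique(dup), collapse = ", "))
  pos1 <- suppressWarnings(as.numeric(df$pos))
  if (any(is.na(pos1)))
    stop("probe manifest ", path, ": non-numeric pos for probe ",
         df$probe_id[which(is.na(pos1))[1L]])
  if (any(pos1 < 1))
    stop("probe manifest ", path, ": pos must be >= 1 (1-based input)")
  rel_raw <- trimws(df$island_relation)
  rel_raw[is.na(rel_raw)] <- ""   # blank field: outside any island zone
  alias_idx <- match(rel_raw, names(island_relation_aliases))
  if (anyNA(alias_idx))
    stop("probe manifest ", path, ": unknown island_relation value(s) ",
         paste(unique(rel_raw[is.na(alias_idx)]), collapse = ", "))
  out <- data.frame(probe_id = df$probe_id,
                    chrom = trimws(df$chrom),
                    pos = pos1 - 1,
                    island_relation =
                      unname(island_relation_aliases[alias_idx]),
                    stringsAsFactors = FALSE)
  out$gene_symbols <- split_list_field(df[["gene_symbols"]], nrow(out))
  out$region_flags <- split_list_field(df[["region_flags"]], nrow(out))
  message("read_probe_manifest: ", nrow(out), " probes from ", path)
  class(out) <- c("ProbeManifest", "data.frame")
  out
}

split_list_field <- function(x, n) {
  if (is.null(x)) return(replicate(n, character(0), simplify = FALSE))
  lapply(x, function(s) {
    if (is.na(s)) return(character(0))
    s <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    s[nzchar(s)]
  })
}

#' Read a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `condition`, `donor`.
#' Conditions must be `reference` and `treatment` with at least two samples
#' each; when the design is paired, donors must form a bijection between
#' the two conditions.
#'
#' @param path Path to the sample sheet TSV.
#' @return A `data.frame` with columns `sample_id`, `condition`, `donor`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "condition", "donor")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("sample sheet ", path, ": missing mandatory column ",
         paste(miss, collapse = ", "))
  validate_sample_sheet(df)
  df[required]
}

validate_sample_sheet <- function(sheet, paired = FALSE) {
  bad <- setdiff(unique(sheet$condition), c("reference", "treatment"))
  if (length(bad))
    stop("sample sheet: condition must be 'reference' or 'treatment', got ",
         paste(bad, collapse = ", "))
  n <- table(factor(sheet$condition, c("reference", "treatment")))
  if (any(n < 2L))
    stop("sample sheet: need >= 2 samples per condition (have ",
         n[["reference"]], " reference, ", n[["treatment"]], " treatment)")
  if (anyDuplicated(sheet$sample_id))
    stop("sample sheet: duplicate sample_id")
  if (paired) {
    ref <- sheet$donor[sheet$condition == "reference"]
    trt <- sheet$donor[sheet$condition == "treatment"]
    if (anyDuplicated(ref) || anyDuplicated(trt) ||
        !setequal(ref, trt) || length(ref) != length(trt))
      stop("sample sheet: paired design requires donors to pair one ",
           "reference with one treatment sample")
  }
  invisible(sheet)
}

#' Read genomic intervals from a BED-family file
#'
#' Supports plain BED3+ and ENCODE narrowPeak. Coordinates are 0-based
#' half-open in the file and are kept unchanged. `track`, `browser` and `#`
#' comment lines are skipped. For both dialects column 4, when present, is
#' retained as the interval label; further columns are ignored.
#'
#' @param path Path to the BED file.
#' @param dialect `"bed3plus"` or `"narrowPeak"` (same parsing; the dialect
#'   is recorded for provenance).
#' @return A `data.frame` of intervals (`chrom`, `start`, `end`, `label`).
#' @export
read_bed <- function(path, dialect = c("bed3plus", "narrowPeak")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  skipped <- sum(!keep)
  idx <- which(keep)
  if (!length(idx)) {
    message("read_bed: 0 intervals from ", path)
    return(genomic_intervals(character(0), numeric(0), numeric(0),
                             label = character(0)))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED ", path, ": fewer than 3 fields at line ", idx[which(nf < 3L)[1L]])
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.numeric(s_chr))
  end <- suppressWarnings(as.numeric(e_chr))
  nonint <- which(is.na(start) | is.na(end) |
                    start != floor(start) | end != floor(end))
  if (length(nonint))
    stop("BED ", path, ": non-integer coordinate at line ", idx[nonint[1L]])
  rev_iv <- which(start >= end)
  if (length(rev_iv))
    stop("BED ", path, ": start >= end at line ", idx[rev_iv[1L]])
  label <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  iv <- data.frame(chrom = trimws(chrom), start = start, end = end,
                   label = label, stringsAsFactors = FALSE)
  validate_intervals(iv, where = paste0("BED ", path))
  message("read_bed: ", nrow(iv), " intervals from ", path,
          " (", skipped, " header/blank lines skipped)")
  iv
}

#' Read a numeric matrix with row and column identifiers
#'
#' Tab-separated; the first column holds row ids, the header gives the
#' column (sample) ids. Cells must be numeric or the literal `NA`; missing
#' values are kept as `NA`, never imputed. Ragged rows and non-numeric
#' cells are hard errors.
#'
#' @param path Path to the matrix TSV.
#' @return A numeric matrix with `rownames` and `colnames`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("matrix ", path, ": empty file")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  # Header names the row-id column first, then one cell per data column;
  # every row must have exactly as many fields as the header.
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("matrix ", path, ": ragged rows (row ", bad[1L], " has ",
         nf[bad[1L]], " fields, header has ", length(header), ")")
  ncol_data <- length(header) - 1L
  col_ids <- header[-1L]
  row_ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(row_ids))
    stop("matrix ", path, ": duplicate row id ",
         row_ids[duplicated(row_ids)][1L])
  cells <- unlist(lapply(fields, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !(cells %in% c("NA", "na", "NaN")))
  if (length(bad))
    stop("matrix ", path, ": non-numeric cell '", cells[bad[1L]], "'")
  m <- matrix(vals, nrow = length(body), ncol = ncol_data, byrow = TRUE,
              dimnames = list(row_ids, col_ids))
  n_missing <- sum(is.na(m))
  message("read_matrix: ", nrow(m), " x ", ncol(m), " from ", path,
          if (n_missing) paste0(" (", n_missing, " NA cells)") else "")
  m
}

#' Write a result table as TSV
#'
#' Writes a tab-separated file with a header row. Floating-point columns are
#' rendered with 15 significant digits so that a `read_matrix` round trip
#' reproduces values within 1e-9. Row order is deterministic: when the table
#' carries a `sort_key` attribute (e.g. `"log2_rrt"` on a TFR report) rows
#' are ordered ascending by that column, otherwise the input order is kept.
#'
#' @param table A `data.frame` with homogeneous rows.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(table, path) {
  stopifnot(is.data.frame(table))
  key <- attr(table, "sort_key")
  if (!is.null(key) && key %in% names(table) && nrow(table) > 1L)
    table <- table[order(table[[key]]), , drop = FALSE]
  out <- table
  for (j in seq_along(out)) {
    if (is.list(out[[j]]))
      out[[j]] <- vapply(out[[j]], paste, "", collapse = ";")
    else if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

# Matrix writer: first column 'id', then sample columns; used for beta/M and
# expression matrices emitted by the simulator.
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 15,
                                               format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
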