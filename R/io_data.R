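#' Column mapping for long-format screening tables
#'
#' Describes how the columns of a long-format drug-combination CSV map onto
#' the fields the package needs. Defaults follow the synergyfinder long
#' layout. `response_kind` says whether the response column carries percent
#' inhibition (used as-is) or percent viability (converted with
#' [viability_to_inhibition()] by [read_long_table()]).
#'
#' @param block_id,drug_row,drug_col,conc_row,conc_col,response column names.
#' @param cell_line,replicate optional column names (`NULL` if absent).
#' @param response_kind `"inhibition"` or `"viability"`.
#' @return a `long_format_spec` list.
#' @export
long_format_spec <- function(block_id = "block_id", drug_row = "drug_row",
                             drug_col = "drug_col", conc_row = "conc_r",
                             conc_col = "conc_c", response = "response",
                             cell_line = "cell_line", replicate = "replicate",
                             response_kind = c("inhibition", "viability")) {
  response_kind <- match.arg(response_kind)
  structure(list(block_id = block_id, drug_row = drug_row,
                 drug_col = drug_col, conc_row = conc_row,
                 conc_col = conc_col, response = response,
                 cell_line = cell_line, replicate = replicate,
                 response_kind = response_kind),
            class = "long_format_spec")
}

#' Read a long-format dose-response table
#'
#' Reads one CSV row per measured well: a drug pair, the two concentrations,
#' the response, and optionally cell line and replicate. Zero concentration of
#' one drug encodes the other drug's monotherapy; `(0, 0)` rows are untreated
#' controls. Viability responses are converted to percent inhibition
#' (`100 - viability`); out-of-range values from experimental noise are
#' retained, not clipped.
#'
#' @param path CSV file path.
#' @param format_spec a [long_format_spec()].
#' @return a `response_records` data frame with standardised columns
#'   `block_id`, `drug_row`, `drug_col`, `conc_row`, `conc_col`, `inhibition`,
#'   `cell_line`, `replicate`.
#' @export
read_long_table <- function(path, format_spec = long_format_spec()) {
  if (!file.exists(path))
    stop_combosens("input file not found: ", path,
                   class = "combosens_io_error")
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  mandatory <- c("block_id", "drug_row", "drug_col", "conc_row", "conc_col",
                 "response")
  for (field in mandatory) {
    col <- format_spec[[field]]
    if (!col %in% names(raw))
      stop_combosens("mandatory column '", col, "' (", field,
                     ") missing from ", path,
                     class = "combosens_config_error")
  }
  n <- nrow(raw)
  get_num <- function(field) {
    v <- raw[[format_spec[[field]]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad))
      stop_combosens("non-numeric ", field, " in ", path, " at data row(s) ",
                     paste(utils::head(bad, 5), collapse = ", "),
                     class = "combosens_parse_error")
    num
  }
  opt <- function(field, default) {
    col <- format_spec[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else
      rep(default, n)
  }
  response <- get_num("response")
  inhibition <- if (format_spec$response_kind == "viability")
    viability_to_inhibition(response) else response
  out <- data.frame(
    block_id = as.character(raw[[format_spec$block_id]]),
    drug_row = as.character(raw[[format_spec$drug_row]]),
    drug_col = as.character(raw[[format_spec$drug_col]]),
    conc_row = get_num("conc_row"),
    conc_col = get_num("conc_col"),
    inhibition = inhibition,
    cell_line = as.character(opt("cell_line", NA_character_)),
    replicate = as.integer(opt("replicate", 1L)),
    stringsAsFactors = FALSE
  )
  if (any(out$conc_row < 0, na.rm = TRUE) ||
      any(out$conc_col < 0, na.rm = TRUE))
    stop_combosens("negative concentrations in ", path,
                   class = "combosens_parse_error")
  attr(out, "response_kind") <- format_spec$response_kind
  class(out) <- c("response_records", class(out))
  out
}

#' @rdname read_long_table
#' @param records a `response_records` data frame.
#' @export
write_long_table <- function(records, path) {
  df <- as.data.frame(records)
  names(df)[names(df) == "conc_row"] <- "conc_r"
  names(df)[names(df) == "conc_col"] <- "conc_c"
  names(df)[names(df) == "inhibition"] <- "response"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert percent viability to percent inhibition
#'
#' `inhibition = 100 - viability`, applied literally: viabilities above 100
#' (noise) give negative inhibition, which is retained until curve-fitting
#' time.
#'
#' @param v percent viability, finite.
#' @return percent inhibition.
#' @examples
#' viability_to_inhibition(c(100, 0, 110))
#' @export
viability_to_inhibition <- function(v) {
  if (any(!is.finite(v)))
    stop_combosens("non-finite viability value",
                   class = "combosens_value_error")
  100 - v
}

#' Assemble a dose-response matrix from one block's records
#'
#' Averages replicates per (conc_row, conc_col) cell into a grid of mean
#' percent inhibition with replicate counts. Cells never measured are `NA`
#' (ragged grids allowed); downstream operations that need a complete row or
#' column fail loudly rather than impute.
#'
#' @param records `response_records` rows sharing one `block_id`.
#' @return a `dose_response_matrix`: list with `block_id`, `drug_row`,
#'   `drug_col`, `cell_line`, `row_concs`, `col_concs`, `inhibition` (matrix),
#'   `n_replicates` (matrix).
#' @export
build_matrix <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    stop_combosens("no records", class = "combosens_value_error")
  if (length(unique(records$block_id)) != 1L)
    stop_combosens("records span multiple block_ids",
                   class = "combosens_integrity_error")
  if (length(unique(records$drug_row)) != 1L ||
      length(unique(records$drug_col)) != 1L)
    stop_combosens("conflicting drug names within block ",
                   records$block_id[1], class = "combosens_integrity_error")
  row_concs <- sort(unique(records$conc_row))
  col_concs <- sort(unique(records$conc_col))
  key_r <- match(records$conc_row, row_concs)
  key_c <- match(records$conc_col, col_concs)
  sums <- matrix(0, length(row_concs), length(col_concs))
  counts <- matrix(0L, length(row_concs), length(col_concs))
  for (i in seq_len(nrow(records))) {
    sums[key_r[i], key_c[i]] <- sums[key_r[i], key_c[i]] +
      records$inhibition[i]
    counts[key_r[i], key_c[i]] <- counts[key_r[i], key_c[i]] + 1L
  }
  inhibition <- ifelse(counts > 0, sums / counts, NA_real_)
  dimnames(inhibition) <- dimnames(counts) <-
    list(format(row_concs, trim = TRUE), format(col_concs, trim = TRUE))
  structure(
    list(block_id = records$block_id[1], drug_row = records$drug_row[1],
         drug_col = records$drug_col[1], cell_line = records$cell_line[1],
         row_concs = row_concs, col_concs = col_concs,
         inhibition = inhibition, n_replicates = counts),
    class = "dose_response_matrix"
  )
}

#' Split records into per-block matrices
#'
#' @param records a `response_records` data frame (any number of blocks).
#' @return named list of [build_matrix()] results, one per block.
#' @export
build_matrices <- function(records) {
  records <- as.data.frame(records)
  blocks <- split(records, records$block_id)
  lapply(blocks, build_matrix)
}

#' Extract the cross-design row and column anchored at the IC50s
#'
#' For each drug, the anchor is the tested nonzero concentration closest to
#' its IC50 on the log10 scale (dose spacing is logarithmic); on an exact
#' log-distance tie the lower concentration is chosen with a warning.
#' `curve1` titrates the column drug over the row drug fixed at its anchor;
#' `curve2` titrates the row drug over the column drug fixed at its anchor.
#' Zero-dose cells are excluded from both vectors; monotherapy vectors (the
#' partner at dose 0) are attached when margins exist.
#'
#' @param matrix a `dose_response_matrix`.
#' @param ic50_row,ic50_col positive IC50s of the row and column drugs.
#' @return a `cross_design_record`: list with `block_id`, `background1_conc`
#'   (row-drug anchor), `curve1_points`, `background2_conc` (column-drug
#'   anchor), `curve2_points`, `mono1_points`, `mono2_points`; each points
#'   element is a data frame `(conc, inhibition)` with `NA` cells dropped.
#' @export
extract_cross <- function(matrix, ic50_row, ic50_col) {
  stopifnot(inherits(matrix, "dose_response_matrix"))
  if (!(ic50_row > 0 && ic50_col > 0))
    stop_combosens("IC50 anchors must be positive",
                   class = "combosens_value_error")
  nz_r <- matrix$row_concs[matrix$row_concs > 0]
  nz_c <- matrix$col_concs[matrix$col_concs > 0]
  if (length(nz_r) < 2L || length(nz_c) < 2L)
    stop_combosens("need at least 2 nonzero concentrations per drug",
                   class = "combosens_design_error")
  anchor_row <- nearest_log_conc(nz_r, ic50_row)
  anchor_col <- nearest_log_conc(nz_c, ic50_col)
  i_r <- match(anchor_row, matrix$row_concs)
  i_c <- match(anchor_col, matrix$col_concs)
  nz_ri <- which(matrix$row_concs > 0)
  nz_ci <- which(matrix$col_concs > 0)

  curve1 <- data.frame(conc = matrix$col_concs[nz_ci],
                       inhibition = matrix$inhibition[i_r, nz_ci])
  curve2 <- data.frame(conc = matrix$row_concs[nz_ri],
                       inhibition = matrix$inhibition[nz_ri, i_c])
  curve1 <- curve1[!is.na(curve1$inhibition), , drop = FALSE]
  curve2 <- curve2[!is.na(curve2$inhibition), , drop = FALSE]

  mono1 <- mono2 <- NULL
  if (0 %in% matrix$col_concs) {
    j0 <- match(0, matrix$col_concs)
    mono1 <- data.frame(conc = matrix$row_concs[nz_ri],
                        inhibition = matrix$inhibition[nz_ri, j0])
    mono1 <- mono1[!is.na(mono1$inhibition), , drop = FALSE]
  }
  if (0 %in% matrix$row_concs) {
    i0 <- match(0, matrix$row_concs)
    mono2 <- data.frame(conc = matrix$col_concs[nz_ci],
                        inhibition = matrix$inhibition[i0, nz_ci])
    mono2 <- mono2[!is.na(mono2$inhibition), , drop = FALSE]
  }
  structure(
    list(block_id = matrix$block_id, drug_row = matrix$drug_row,
         drug_col = matrix$drug_col, cell_line = matrix$cell_line,
         background1_conc = anchor_row, curve1_points = curve1,
         background2_conc = anchor_col, curve2_points = curve2,
         mono1_points = mono1, mono2_points = mono2),
    class = "cross_design_record"
  )
}

nearest_log_conc <- function(concs, ic50) {
  d <- abs(log10(concs) - log10(ic50))
  best <- which(d <= min(d) + 1e-12)
  if (length(best) > 1L) {
    warning("anchor tie at IC50 ", ic50,
            ": choosing the lower concentration")
    best <- best[which.min(concs[best])]
  }
  concs[best]
}
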