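# Readers and writers for the external formats the pipeline consumes:
# MAF-style mutation tables, GMT gene-set collections, clinical tables,
# expression matrices and drug-response tables.  All readers normalize gene
# symbols identically (uppercase, whitespace-trimmed) so downstream joins
# are exact; no alias mapping is attempted.

#' Default nonsilent variant classification vocabulary
#'
#' The variant classes counted as nonsilent by [compute_burden()] and
#' [compute_tmb()].  The set follows common MAF practice (protein-altering
#' SNVs and small indels plus splice and translation-start changes) and is
#' configurable everywhere it is used.
#'
#' @return Character vector of variant classification labels.
#' @export
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Normalize gene symbols
#'
#' Uppercases and trims whitespace.  No alias resolution: symbols from
#' different annotation vintages must be harmonized upstream.
#'
#' @param x character vector of symbols.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# read a delimited file, sniffing the separator from the extension
# (.csv / .csv.gz -> comma, otherwise tab); gzip handled by R connections
read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  base <- sub("\\.gz$", "", path)
  sep <- if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
  out <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(out) == 0L) stop("empty file: ", path)
  out
}

#' Construct a mutation table
#'
#' Long-form somatic variant records keyed by sample and gene.  Symbols are
#' normalized, blank sample or gene entries are dropped (with a warning),
#' and variant classes outside `class_vocab` are preserved but flagged.
#'
#' @param sample_id,gene,variant_class,protein_change character vectors of
#'   equal length (`protein_change` may be `NULL`).
#' @param class_vocab recognized variant classification vocabulary.
#' @return A `data.frame` of class `"mutation_table"` with columns
#'   `sample_id`, `gene`, `variant_class`, `protein_change`.  Attribute
#'   `n_dropped` counts invalid rows removed; `unknown_classes` lists
#'   variant classes outside the vocabulary.
#' @export
mutation_table <- function(sample_id, gene, variant_class,
                           protein_change = NULL,
                           class_vocab = nonsilent_classes()) {
  sample_id <- trimws(as.character(sample_id))
  gene <- normalize_symbols(gene)
  variant_class <- trimws(as.character(variant_class))
  if (is.null(protein_change)) protein_change <- NA_character_
  protein_change <- as.character(protein_change)
  df <- data.frame(sample_id = sample_id, gene = gene,
                   variant_class = variant_class,
                   protein_change = protein_change,
                   stringsAsFactors = FALSE)
  bad <- !nzchar(df$sample_id) | !nzchar(df$gene) |
    is.na(df$sample_id) | is.na(df$gene)
  if (any(bad)) {
    warning(sum(bad), " record(s) with blank sample or gene dropped")
    df <- df[!bad, , drop = FALSE]
  }
  unknown <- setdiff(unique(df$variant_class), class_vocab)
  if (length(unknown)) {
    message("variant classes outside vocabulary (kept, flagged): ",
            paste(unknown, collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, class = c("mutation_table", "data.frame"),
            n_dropped = sum(bad), unknown_classes = unknown)
}

#' Read a MAF-style mutation table
#'
#' @param path TSV/CSV file (optionally gzipped) with one variant per row.
#' @param sample_col,gene_col,class_col,protein_col column names for the
#'   sample barcode, gene symbol, variant classification and (optional)
#'   protein change; defaults follow MAF conventions.
#' @param class_vocab recognized variant classes (see [nonsilent_classes()]).
#' @return A [mutation_table()].
#' @export
read_mutation_table <- function(path,
                                sample_col = "Tumor_Sample_Barcode",
                                gene_col = "Hugo_Symbol",
                                class_col = "Variant_Classification",
                                protein_col = "Protein_Change",
                                class_vocab = nonsilent_classes()) {
  df <- read_delim_sniff(path)
  need <- c(sample_col, gene_col, class_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("mutation table is missing mapped column(s): ",
         paste(miss, collapse = ", "))
  }
  prot <- if (protein_col %in% names(df)) df[[protein_col]] else NULL
  out <- mutation_table(df[[sample_col]], df[[gene_col]], df[[class_col]],
                        prot, class_vocab = class_vocab)
  message("read ", nrow(df), " rows, kept ", nrow(out),
          ", dropped ", attr(out, "n_dropped"))
  out
}

#' Write a mutation table as MAF-style TSV
#'
#' @param x a [mutation_table()].
#' @param path output path.
#' @export
write_mutation_table <- function(x, path) {
  stopifnot(inherits(x, "mutation_table"))
  out <- data.frame(Tumor_Sample_Barcode = x$sample_id,
                    Hugo_Symbol = x$gene,
                    Variant_Classification = x$variant_class,
                    Protein_Change = x$protein_change,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description (discarded), then member symbols.
#' Duplicate members within a set are deduplicated; duplicate set names are
#' an error.
#'
#' @param path GMT file (optionally gzipped).
#' @param source label stored with the collection (defaults to the file name).
#' @return Named list of character vectors, class `"gene_set_collection"`,
#'   attribute `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate gene-set name(s): ",
                        paste(unique(dup), collapse = ", "))
  sets <- lapply(fields, function(f) unique(normalize_symbols(f[-(1:2)])))
  names(sets) <- nm
  gene_set_collection(sets, source = source)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member symbols.
#' @param source provenance label.
#' @return Class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets <- lapply(sets, function(s) unique(normalize_symbols(s)))
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set(s) present")
  structure(sets, class = "gene_set_collection", source = source)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, length, 1L)
  cat("Gene-set collection (", attr(x, "source"), "): ", length(x),
      " sets, sizes ", min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Read a clinical table
#'
#' @param path TSV/CSV with one sample per row.
#' @param sample_col,time_col,event_col column names for the sample id,
#'   survival time and event indicator.
#' @param time_factor multiplier converting the stored time unit to months
#'   (e.g. `1/30.44` for days).
#' @param covariates optional character vector of covariate columns to keep.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path, sample_col = "sample_id",
                          time_col = "time", event_col = "event",
                          time_factor = 1, covariates = NULL) {
  df <- read_delim_sniff(path)
  need <- c(sample_col, time_col, event_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table is missing column(s): ",
                         paste(miss, collapse = ", "))
  cov <- NULL
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(df))
    if (length(miss)) stop("missing covariate column(s): ",
                           paste(miss, collapse = ", "))
    cov <- df[covariates]
  }
  clinical_table(sample_id = df[[sample_col]],
                 time = as.numeric(df[[time_col]]) * time_factor,
                 event = df[[event_col]], covariates = cov)
}

#' Construct a clinical table
#'
#' Survival times are stored in months and must be strictly positive; the
#' event indicator is 1 for an observed event, 0 for right censoring.
#'
#' @param sample_id unique sample identifiers.
#' @param time survival time in months, `> 0`.
#' @param event 0/1 event indicator.
#' @param covariates optional data.frame of per-sample covariates; factor
#'   columns keep their level order (reference level first).
#' @return A `data.frame` of class `"clinical_table"` with columns
#'   `sample_id`, `time`, `event` and any covariates.
#' @export
clinical_table <- function(sample_id, time, event, covariates = NULL) {
  sample_id <- trimws(as.character(sample_id))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in clinical table")
  time <- as.numeric(time)
  bad <- !is.finite(time) | time <= 0
  if (any(bad)) {
    stop("non-positive or non-finite survival time for sample(s): ",
         paste(sample_id[bad], collapse = ", "))
  }
  event <- as.numeric(event)
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  df <- data.frame(sample_id = sample_id, time = time, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    stopifnot(nrow(covariates) == nrow(df))
    df <- cbind(df, covariates)
  }
  rownames(df) <- NULL
  structure(df, class = c("clinical_table", "data.frame"))
}

#' Read a log-scale expression matrix
#'
#' Genes in rows, samples in columns, first column = gene symbol.  Duplicate
#' gene labels are collapsed to the row with the highest variance (first
#' occurrence on ties), with a warning.
#'
#' @param path TSV/CSV (optionally gzipped).
#' @return Numeric matrix genes x samples with normalized rownames.
#' @export
read_expression <- function(path) {
  df <- read_delim_sniff(path)
  genes <- normalize_symbols(df[[1L]])
  mat <- as.matrix(df[-1L])
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat))) stop("non-finite values in expression matrix")
  rownames(mat) <- genes
  collapse_duplicate_genes(mat)
}

# keep the highest-variance row per duplicated gene label (first wins ties)
collapse_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  warning("duplicate gene labels collapsed to the highest-variance row")
  v <- apply(mat, 1L, stats::var)
  ord <- order(rownames(mat), -v)        # within gene: decreasing variance,
  ord <- ord[!duplicated(rownames(mat)[ord])]  # stable first on ties
  mat[sort(ord), , drop = FALSE]
}

#' Read a drug-response table
#'
#' @param path TSV/CSV with one (cell line, drug) measurement per row.
#' @param cell_col,drug_col,ic50_col column names for cell line, drug and
#'   natural-log IC50.
#' @param moa_col,target_col optional annotation columns.
#' @return A `data.frame` of class `"drug_response_table"` with columns
#'   `cell_line`, `drug`, `ln_ic50` (+ `moa`, `target` if present).
#' @export
read_drug_response <- function(path, cell_col = "cell_line",
                               drug_col = "drug", ic50_col = "ln_ic50",
                               moa_col = NULL, target_col = NULL) {
  df <- read_delim_sniff(path)
  need <- c(cell_col, drug_col, ic50_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug-response table is missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(cell_line = as.character(df[[cell_col]]),
                    drug = as.character(df[[drug_col]]),
                    ln_ic50 = as.numeric(df[[ic50_col]]),
                    stringsAsFactors = FALSE)
  if (!is.null(moa_col) && moa_col %in% names(df)) out$moa <- df[[moa_col]]
  if (!is.null(target_col) && target_col %in% names(df)) {
    out$target <- df[[target_col]]
  }
  if (any(!is.finite(out$ln_ic50))) stop("non-finite ln_ic50 values")
  if (anyDuplicated(out[c("cell_line", "drug")])) {
    stop("duplicate (cell_line, drug) pairs")
  }
  structure(out, class = c("drug_response_table", "data.frame"))
}
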