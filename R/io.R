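#' @useDynLib upstreamx, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median p.adjust pnorm rbinom rnbinom rpois runif
#'   rlnorm sd setNames fisher.test quantile dpois dnbinom var
#' @importFrom utils read.delim write.table combn head modifyList
"_PACKAGE"

# ---- promoters (FASTA) -------------------------------------------------

#' Read promoter sequences from a FASTA file
#'
#' Promoters are expected to be fixed-length windows around the TSS
#' (by default 1100 bp, -1000..+100, so the TSS sits at 0-based index 1000,
#' i.e. `length - 100`). Sequences are uppercased on read and must be over
#' the alphabet `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file. The gene id is the first
#'   whitespace-delimited token of each header.
#' @return A `promoter_set`: a data.frame with columns `gene_id`,
#'   `sequence` and `tss_offset`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate id ", dup[[1L]], call. = FALSE)
  sequence <- toupper(as.character(seqs))
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[[1L]]
    stop(sprintf("non-DNA character in record '%s' at position %d",
                 ids[[i]], bad[[i]]), call. = FALSE)
  }
  promoter_set(ids, sequence)
}

#' Construct a promoter set
#'
#' @param gene_id Character vector of gene ids.
#' @param sequence Character vector of uppercase DNA sequences.
#' @param tss_offset 0-based index of the TSS within each sequence;
#'   defaults to `nchar(sequence) - 100` (the -1000..+100 convention),
#'   clamped to 0 for sequences shorter than 100 bp.
#' @return A `promoter_set` data.frame.
#' @export
promoter_set <- function(gene_id, sequence, tss_offset = NULL) {
  if (is.null(tss_offset))
    tss_offset <- pmax(0L, nchar(sequence) - 100L)
  stopifnot(length(gene_id) == length(sequence),
            !anyDuplicated(gene_id),
            all(tss_offset >= 0L), all(tss_offset < nchar(sequence)))
  structure(
    data.frame(gene_id = as.character(gene_id),
               sequence = as.character(sequence),
               tss_offset = as.integer(tss_offset),
               stringsAsFactors = FALSE),
    class = c("promoter_set", "data.frame"))
}

#' Write promoters to a normalized FASTA file
#'
#' One header line and one (unwrapped) sequence line per record, so that
#' `write_fasta(read_fasta(f))` is byte-identical to a normalized `f`.
#'
#' @param x A `promoter_set`.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", x$gene_id, "\n", x$sequence), con, sep = "\n")
  invisible(path)
}

# ---- PWMs (TRANSFAC flat file) -----------------------------------------

#' Construct a position weight matrix
#'
#' @param name Matrix identifier.
#' @param counts Numeric L x 4 matrix of per-position base counts or
#'   frequencies, columns A, C, G, T.
#' @param pseudocount Pseudo-frequency added before any log operation
#'   (default 0.01).
#' @param core_length Length of the high-information "core" block used for
#'   the core similarity score (default 5).
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, counts, pseudocount = 0.01, core_length = 5L) {
  counts <- as.matrix(counts)
  stopifnot(is.character(name), length(name) == 1L,
            ncol(counts) == 4L, nrow(counts) >= 1L,
            all(counts >= 0), all(rowSums(counts) > 0),
            pseudocount >= 0)
  colnames(counts) <- c("A", "C", "G", "T")
  structure(list(name = name, counts = counts,
                 pseudocount = pseudocount,
                 core_length = as.integer(min(core_length, nrow(counts)))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, pseudocount %g\n",
              x$name, nrow(x$counts), x$pseudocount))
  invisible(x)
}

#' Per-position base frequencies of a PWM
#'
#' Rows are normalized to sum to one; the pseudocount is added as a
#' frequency and renormalized, so each returned row sums to 1 exactly.
#'
#' @param x A `pwm`.
#' @return L x 4 matrix of frequencies.
#' @export
pwm_freq <- function(x) {
  f0 <- x$counts / rowSums(x$counts)
  (f0 + x$pseudocount) / (1 + 4 * x$pseudocount)
}

#' Read a TRANSFAC-style matrix flat file
#'
#' Parses the classic dialect: `AC`/`ID` header lines, a `P0` column
#' header, consecutively numbered rows `01  a c g t [consensus]`, and a
#' `//` record terminator. Count and frequency rows are both accepted;
#' matrices are normalized to frequencies on use.
#'
#' @param path Path to the flat file.
#' @param pseudocount Pseudocount stored on each parsed matrix.
#' @return A list of `pwm` objects, named by matrix id.
#' @export
read_transfac_matrices <- function(path, pseudocount = 0.01) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  pwms <- list()
  cur_name <- NULL; cur_ac <- NULL; rows <- list(); expect <- 1L
  in_record <- FALSE
  flush_record <- function() {
    if (length(rows) == 0L)
      stop("matrix record with no rows", call. = FALSE)
    nm <- if (!is.null(cur_name)) cur_name else cur_ac
    if (is.null(nm)) stop("matrix record with no ID/AC line", call. = FALSE)
    pwm(nm, do.call(rbind, rows), pseudocount = pseudocount)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^//", ln)) {
      pwms[[length(pwms) + 1L]] <- flush_record()
      cur_name <- NULL; cur_ac <- NULL; rows <- list(); expect <- 1L
      in_record <- FALSE
      next
    }
    if (grepl("^AC\\s", ln)) {
      cur_ac <- sub("^AC\\s+", "", ln); in_record <- TRUE
    } else if (grepl("^ID\\s", ln)) {
      cur_name <- sub("^ID\\s+", "", ln); in_record <- TRUE
    } else if (grepl("^P0", ln) || grepl("^PO", ln)) {
      in_record <- TRUE
    } else if (grepl("^[0-9][0-9]\\s", ln)) {
      in_record <- TRUE
      fields <- strsplit(trimws(ln), "\\s+")[[1L]]
      rownum <- suppressWarnings(as.integer(fields[[1L]]))
      if (is.na(rownum) || rownum != expect)
        stop(sprintf("line %d: expected row %02d, got '%s'",
                     i, expect, fields[[1L]]), call. = FALSE)
      vals <- suppressWarnings(as.numeric(fields[-1L]))
      # last field may be a consensus letter
      if (length(vals) >= 1L && is.na(vals[[length(vals)]]))
        vals <- vals[-length(vals)]
      if (length(vals) != 4L || anyNA(vals))
        stop(sprintf("line %d: matrix row needs 4 numeric fields", i),
             call. = FALSE)
      rows[[expect]] <- vals
      expect <- expect + 1L
    }
  }
  if (in_record || length(rows) > 0L)
    stop("missing '//' terminator at end of file", call. = FALSE)
  names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  pwms
}

#' Write PWMs in the TRANSFAC flat-file dialect
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @export
write_transfac_matrices <- function(pwms, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(paste0("AC  ", p$name), paste0("ID  ", p$name),
                 "P0      A      C      G      T"), con)
    for (i in seq_len(nrow(p$counts)))
      writeLines(sprintf("%02d  %g  %g  %g  %g", i,
                         p$counts[i, 1], p$counts[i, 2],
                         p$counts[i, 3], p$counts[i, 4]), con)
    writeLines("//", con)
  }
  invisible(path)
}

# ---- signaling network -------------------------------------------------

#' Construct a directed signaling network
#'
#' Edges point downstream: `source` acts upstream of `target`. Self-loops
#' are dropped with a warning; `tf_nodes` flags the transcription-factor
#' nodes that the master-regulator search treats as scoring targets.
#'
#' @param edges Data.frame with character columns `source`, `target`.
#' @param tf_nodes Character vector of TF node ids.
#' @param nodes Optional full node set (defaults to every node seen in
#'   `edges` plus `tf_nodes`).
#' @return An object of class `signaling_network`.
#' @export
signaling_network <- function(edges, tf_nodes = character(), nodes = NULL) {
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  if (is.null(nodes))
    nodes <- unique(c(edges$source, edges$target, tf_nodes))
  nodes <- as.character(nodes)
  stopifnot(all(edges$source %in% nodes), all(edges$target %in% nodes),
            all(tf_nodes %in% nodes))
  structure(list(nodes = nodes, edges = edges,
                 tf_nodes = unique(as.character(tf_nodes))),
            class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("signaling_network: %d nodes, %d edges, %d TFs\n",
              length(x$nodes), nrow(x$edges), length(x$tf_nodes)))
  invisible(x)
}

#' Read a signaling network from an edge-list TSV
#'
#' Expects the header `source  target  target_is_tf`; the flag must be one
#' of 0/1/true/false (case-insensitive). A node is a TF if it ever appears
#' as a target with a true flag.
#'
#' @param path Path to the TSV file.
#' @return A `signaling_network`.
#' @export
read_network <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, colClasses = "character", comment.char = "#")
  stopifnot(identical(colnames(df)[1:3], c("source", "target", "target_is_tf")))
  flag <- tolower(df$target_is_tf)
  ok <- flag %in% c("0", "1", "true", "false")
  if (!all(ok))
    stop("invalid target_is_tf value '", df$target_is_tf[!ok][[1L]], "'",
         call. = FALSE)
  is_tf <- flag %in% c("1", "true")
  signaling_network(df[, c("source", "target")],
                    tf_nodes = unique(df$target[is_tf]))
}

#' Write a signaling network to an edge-list TSV
#'
#' @param x A `signaling_network`.
#' @param path Output path.
#' @export
write_network <- function(x, path) {
  df <- data.frame(source = x$edges$source, target = x$edges$target,
                   target_is_tf = as.integer(x$edges$target %in% x$tf_nodes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- count matrix ------------------------------------------------------

#' Construct a count matrix with a sample design
#'
#' @param counts Integer matrix, genes x samples, with row and column names.
#' @param condition_of Named character vector mapping sample id to
#'   condition label.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition_of) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            !anyDuplicated(rownames(counts)), !anyDuplicated(colnames(counts)),
            all(counts >= 0), all(counts == round(counts)))
  missing <- setdiff(colnames(counts), names(condition_of))
  if (length(missing) > 0L)
    stop("sample missing from design: ", missing[[1L]], call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 condition_of = condition_of[colnames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$condition_of), collapse = ", ")))
  invisible(x)
}

#' Read a gene-level count matrix plus its design file
#'
#' @param counts_path TSV with gene ids in the first column and one column
#'   per sample; counts must be non-negative integers.
#' @param design_path Two-column TSV (`sample`, `condition`) mapping each
#'   sample to its condition label.
#' @return A `count_matrix`.
#' @export
read_counts <- function(counts_path, design_path) {
  stopifnot(file.exists(counts_path), file.exists(design_path))
  df <- read.delim(counts_path, check.names = FALSE, comment.char = "#")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene id ", genes[duplicated(genes)][[1L]], call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  m <- matrix(suppressWarnings(as.numeric(m)), nrow = nrow(m),
              dimnames = list(NULL, colnames(m)))
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer count for gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]),
         call. = FALSE)
  rownames(m) <- genes
  design <- read.delim(design_path, colClasses = "character",
                       comment.char = "#")
  count_matrix(m, setNames(design[[2L]], design[[1L]]))
}

#' Write a count matrix and design to TSV files
#'
#' @param x A `count_matrix`.
#' @param counts_path,design_path Output paths.
#' @export
write_counts <- function(x, counts_path, design_path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(x$condition_of),
                         condition = unname(x$condition_of)),
              design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

# ---- generic TSV output with provenance header -------------------------

#' Write a results table with a provenance comment header
#'
#' All pipeline outputs are TSVs prefixed with `#` comment lines recording
#' the tool version, seed and parameters of the producing stage.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param params Named list recorded in the header.
#' @export
write_output_tsv <- function(df, path, params = list()) {
  hdr <- sprintf("# upstreamx %s",
                 as.character(utils::packageVersion("upstreamx")))
  if (length(params) > 0L)
    hdr <- c(hdr, paste0("# ", names(params), "=",
                         vapply(params, function(v)
                           paste(format(v), collapse = ","), character(1))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
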