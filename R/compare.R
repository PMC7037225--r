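# Direction-matched comparison of master-regulator tables across
# treatments, plus category annotation summaries.

#' Construct a regulator table for one treatment
#'
#' @param treatment Treatment label.
#' @param up,down Gene symbols of up- and down-regulated master
#'   regulators; uppercased and deduplicated, must be disjoint.
#' @return An object of class `regulator_table`.
#' @export
regulator_table <- function(treatment, up, down) {
  up <- unique(toupper(up)); down <- unique(toupper(down))
  if (length(intersect(up, down)) > 0L)
    stop("up and down sets overlap: ",
         paste(intersect(up, down), collapse = ", "), call. = FALSE)
  structure(list(treatment = treatment, up = up, down = down),
            class = "regulator_table")
}

#' @export
print.regulator_table <- function(x, ...) {
  cat(sprintf("regulator_table '%s': %d up, %d down\n",
              x$treatment, length(x$up), length(x$down)))
  invisible(x)
}

#' Read regulator tables from a long-format TSV
#'
#' Expects columns `treatment`, `direction` (`up`/`down`), `gene`.
#'
#' @param path Path to the TSV.
#' @return Named list of `regulator_table`s, one per treatment, in file
#'   order.
#' @export
read_regulator_tables <- function(path) {
  df <- read.delim(path, colClasses = "character", comment.char = "#")
  stopifnot(all(c("treatment", "direction", "gene") %in% colnames(df)))
  stopifnot(all(df$direction %in% c("up", "down")))
  out <- lapply(unique(df$treatment), function(tr) {
    d <- df[df$treatment == tr, , drop = FALSE]
    regulator_table(tr, d$gene[d$direction == "up"],
                    d$gene[d$direction == "down"])
  })
  setNames(out, unique(df$treatment))
}

#' The published LDL / latex-bead master-regulator tables
#'
#' Packaged transcription of the direction-resolved master-regulator
#' lists for the four LDL treatment arms (naturally occurring,
#' desialylated, acetylated, oxidized).
#'
#' @return Named list of `regulator_table`s.
#' @export
ldl_master_regulators <- function() {
  read_regulator_tables(system.file("extdata",
                                    "ldl_master_regulators.tsv",
                                    package = "upstreamx",
                                    mustWork = TRUE))
}

#' Direction-matched overlap of two regulator tables
#'
#' A gene matches only if it appears in both tables with the same
#' direction.
#'
#' @param a,b `regulator_table`s.
#' @return `list(matched_up =, matched_down =, n_matched =,
#'   n_b_total =)`.
#' @export
match_directional <- function(a, b) {
  mu <- intersect(a$up, b$up)
  md <- intersect(a$down, b$down)
  list(matched_up = mu, matched_down = md,
       n_matched = length(mu) + length(md),
       n_b_total = length(b$up) + length(b$down))
}

#' Regulators direction-matched with the reference in every table
#'
#' @param tables List of at least one comparison `regulator_table`.
#' @param reference Reference `regulator_table` whose directions must be
#'   matched.
#' @return Character vector of gene symbols.
#' @export
common_to_all <- function(tables, reference) {
  stopifnot(length(tables) >= 1L)
  up <- reference$up; down <- reference$down
  for (tb in tables) {
    m <- match_directional(reference, tb)
    up <- intersect(up, m$matched_up)
    down <- intersect(down, m$matched_down)
  }
  sort(c(up, down))
}

#' Read a category annotation table
#'
#' @param path TSV with columns `gene`, `innate_immunity`,
#'   `lipid_metabolism`, `phagocytosis`; flags must be `+`, `-` or `?`.
#' @return An `annotation_table` data.frame.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, colClasses = "character", comment.char = "#")
  cats <- c("innate_immunity", "lipid_metabolism", "phagocytosis")
  stopifnot(all(c("gene", cats) %in% colnames(df)))
  flags <- unlist(df[cats], use.names = FALSE)
  bad <- setdiff(flags, c("+", "-", "?"))
  if (length(bad) > 0L)
    stop("unknown flag symbol '", bad[[1L]], "'", call. = FALSE)
  df$gene <- toupper(df$gene)
  structure(df, class = c("annotation_table", "data.frame"))
}

#' The packaged functional annotations of the top master regulators
#'
#' @return An `annotation_table` flagging involvement of each of the top
#'   regulators in innate immunity, lipid metabolism and phagocytosis.
#' @export
ldl_annotations <- function() {
  read_annotation_table(system.file("extdata", "ldl_annotations.tsv",
                                    package = "upstreamx",
                                    mustWork = TRUE))
}

#' Count positive category flags
#'
#' @param annotations An `annotation_table`.
#' @return Named integer vector: number of `+` flags per category
#'   (`-` and `?` are not counted).
#' @export
annotation_counts <- function(annotations) {
  cats <- c("innate_immunity", "lipid_metabolism", "phagocytosis")
  vapply(cats, function(cc) sum(annotations[[cc]] == "+"), integer(1))
}

#' Two-set Venn region sizes per direction
#'
#' @param a,b `regulator_table`s.
#' @return Data.frame with one row per direction: `a_only`, `shared`,
#'   `b_only`, plus an attached `totals` attribute `(up, down)` for each
#'   table.
#' @export
venn_counts <- function(a, b) {
  row_of <- function(sa, sb)
    c(a_only = length(setdiff(sa, sb)), shared = length(intersect(sa, sb)),
      b_only = length(setdiff(sb, sa)))
  out <- rbind(up = row_of(a$up, b$up), down = row_of(a$down, b$down))
  out <- as.data.frame(out)
  attr(out, "totals") <- list(a = c(up = length(a$up),
                                    down = length(a$down)),
                              b = c(up = length(b$up),
                                    down = length(b$down)))
  out
}

#' Pairwise comparison report against a reference treatment
#'
#' @param tables Named list of `regulator_table`s.
#' @param reference Name of the reference treatment in `tables`.
#' @return Data.frame with matched counts per comparison table.
#' @export
comparison_report <- function(tables, reference) {
  stopifnot(reference %in% names(tables))
  ref <- tables[[reference]]
  others <- tables[setdiff(names(tables), reference)]
  rows <- lapply(names(others), function(nm) {
    m <- match_directional(ref, others[[nm]])
    data.frame(treatment = nm, n_matched = m$n_matched,
               n_total = m$n_b_total,
               matched_up = paste(sort(m$matched_up), collapse = ","),
               matched_down = paste(sort(m$matched_down), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
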