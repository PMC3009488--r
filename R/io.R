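#' Read protein sequences from a FASTA file
#'
#' IDs are the first whitespace-delimited token of each header;
#' sequences are uppercased; line wrapping and trailing whitespace are
#' tolerated. Duplicate IDs are an error.
#'
#' @param path FASTA file.
#' @return named character vector of sequences in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a sequence-ID to class-label table
#'
#' Tab-separated, two columns (`id`, `label`); lines starting with `#`
#' are comments. Duplicate IDs and malformed lines are errors.
#'
#' @param path label file.
#' @return named character vector mapping id -> label.
#' @export
read_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L)
    stop("malformed label line(s) ", paste(bad, collapse = ", "),
         " in ", path, " (need exactly two tab-separated columns)")
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate IDs in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(vapply(parts, `[[`, character(1), 2), ids)
}

#' Write a label table
#' @param labels named character vector (id -> label).
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  writeLines(paste(names(labels), labels, sep = "\t"), path)
  invisible(path)
}

#' Assemble a labeled dataset from FASTA + label files
#'
#' In strict mode (default) the two ID sets must match exactly; the
#' mismatches are listed otherwise. Labels are returned in FASTA record
#' order.
#'
#' @param fasta_path FASTA file of sequences.
#' @param labels_path tab-separated label table.
#' @param strict require a one-to-one ID join.
#' @return list with `sequences`, `labels` (both named, aligned) and
#'   `provenance`.
#' @export
load_dataset <- function(fasta_path, labels_path, strict = TRUE) {
  sequences <- read_fasta(fasta_path)
  labels <- read_labels(labels_path)
  only_f <- setdiff(names(sequences), names(labels))
  only_l <- setdiff(names(labels), names(sequences))
  if (strict && (length(only_f) > 0L || length(only_l) > 0L))
    stop("FASTA / label table IDs do not match. ",
         if (length(only_f)) paste0("Unlabeled: ",
                                    paste(only_f, collapse = ", "), ". "),
         if (length(only_l)) paste0("No sequence: ",
                                    paste(only_l, collapse = ", "), "."))
  keep <- intersect(names(sequences), names(labels))
  list(sequences = sequences[keep], labels = labels[keep],
       provenance = c(fasta = fasta_path, labels = labels_path))
}

#' Read a flat key=value configuration file
#'
#' Recognized keys (all optional): `normalization`, `gamma`, `C`,
#' `epsilon`, `multiclass_strategy`, `sp_definition`, `stratified`,
#' `seed`, `scheme_set`. Lines starting with `#` are comments. Values
#' that parse as numbers are returned numeric.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    if (v %in% c("TRUE", "true")) return(TRUE)
    if (v %in% c("FALSE", "false")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, trimws(vapply(kv, `[[`, character(1), 1)))
}
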