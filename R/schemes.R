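#' @importFrom methods is
NULL

#' The 20 canonical amino-acid one-letter codes
#'
#' Alphabetical order of the one-letter IUPAC codes. Ambiguity and
#' non-standard codes (B, Z, X, J, U, O) are never part of any scheme.
#'
#' @export
CANONICAL_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Built-in residue classification schemes. Group order is the printed
# left-to-right order; the window limit caps the default k enumeration.
# F-Vc4 is published with R and F missing from every group; they are
# restored as singleton groups so the scheme partitions all 20 residues.
.builtin_schemes <- list(
  "4-Cat"   = list(groups = c("ALVIFWMP", "STYCNGQ", "KRH", "DE"),
                   window_limit = 6L),
  "7-Cat"   = list(groups = c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C"),
                   window_limit = 4L),
  "20-Cat"  = list(groups = c("A", "G", "V", "I", "L", "F", "P", "Y", "M", "T",
                              "S", "H", "N", "Q", "W", "R", "K", "D", "E", "C"),
                   window_limit = 3L),
  "ms"      = list(groups = c("AVLIMC", "WYHF", "TQSN", "RK", "ED", "GP"),
                   window_limit = 4L),
  "lesk"    = list(groups = c("AST", "CVILWYMPF", "HQN", "RK", "ED", "G"),
                   window_limit = 4L),
  "F-Ic4"   = list(groups = c("AWM", "GST", "HPY", "CVIFL", "DNQ", "ER", "K"),
                   window_limit = 4L),
  "F-Ic2"   = list(groups = c("AWM", "GS", "HPY", "CVI", "FL", "DNQ", "ER",
                              "K", "T"),
                   window_limit = 3L),
  "F-IIIc4" = list(groups = c("ACV", "HPL", "DQ", "S", "ERGN", "F", "IMT",
                              "KW", "Y"),
                   window_limit = 3L),
  "F-Vc4"   = list(groups = c("AWHC", "G", "LEPV", "KYMT", "IN", "Q", "D", "S",
                              "R", "F"),
                   window_limit = 3L)
)

#' Construct an amino-acid classification scheme
#'
#' A scheme is a named partition of the 20 canonical residues into
#' groups; recoding a protein over the group indices compresses the
#' alphabet and with it the k-mer feature space from \eqn{20^k} to
#' \eqn{l^k} where \eqn{l} is the number of groups. Each scheme carries
#' a window limit: the largest k enumerated for it by default.
#'
#' @param name short scheme identifier.
#' @param groups character vector, one string of residue letters per
#'   group; groups must be pairwise disjoint and jointly cover the 20
#'   canonical residues.
#' @param window_limit positive integer, maximum default k-mer length.
#' @param validate if `TRUE` (default) reject invalid schemes.
#' @return an object of class `aa_scheme` with fields `name`, `groups`,
#'   `window_limit`, `alphabet_size` and an internal residue-to-group
#'   lookup.
#' @seealso [load_builtin_scheme()], [validate_scheme()]
#' @export
aa_scheme <- function(name, groups, window_limit, validate = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(groups), length(groups) >= 1L)
  window_limit <- as.integer(window_limit)
  groups <- toupper(groups)
  lookup <- integer(0)
  for (g in seq_along(groups)) {
    res <- strsplit(groups[[g]], "", fixed = TRUE)[[1]]
    lookup[res] <- g
  }
  scheme <- structure(
    list(name = name, groups = groups, window_limit = window_limit,
         alphabet_size = length(groups), lookup = lookup),
    class = "aa_scheme")
  if (validate) {
    bad <- validate_scheme(scheme)
    if (length(bad) > 0L)
      stop("invalid scheme '", name, "': ", paste(bad, collapse = "; "))
  }
  scheme
}

#' @export
print.aa_scheme <- function(x, ...) {
  cat(sprintf("Amino-acid classification '%s': %d groups, window limit %d\n",
              x$name, x$alphabet_size, x$window_limit))
  cat(" ", paste(x$groups, collapse = " | "), "\n")
  invisible(x)
}

#' Validate an amino-acid classification scheme
#'
#' Checks the partition property: every canonical residue covered exactly
#' once, no empty group, and a positive window limit. Returns violations
#' rather than raising, so callers can report all defects of a
#' user-supplied scheme at once.
#'
#' @param scheme an `aa_scheme` (or a bare list with `groups` and
#'   `window_limit` fields).
#' @return character vector of violation messages; empty when the scheme
#'   is usable.
#' @export
validate_scheme <- function(scheme) {
  violations <- character(0)
  groups <- toupper(scheme$groups)
  if (any(nchar(groups) == 0L))
    violations <- c(violations, "empty group")
  letters_all <- unlist(strsplit(groups, "", fixed = TRUE))
  dup <- unique(letters_all[duplicated(letters_all)])
  for (r in dup)
    violations <- c(violations, paste0(r, " covered twice"))
  missing <- setdiff(CANONICAL_RESIDUES, letters_all)
  for (r in missing)
    violations <- c(violations, paste0(r, " uncovered"))
  extra <- setdiff(unique(letters_all), CANONICAL_RESIDUES)
  for (r in extra)
    violations <- c(violations, paste0(r, " is not a canonical residue"))
  wl <- scheme$window_limit
  if (is.null(wl) || is.na(wl) || wl < 1)
    violations <- c(violations, "window_limit < 1")
  violations
}

#' Load one of the nine built-in classification schemes
#'
#' Built-ins: `"4-Cat"` (polarity/charge, 4 groups), `"7-Cat"` (7 groups
#' from density-functional/molecular-modelling classification),
#' `"20-Cat"` (identity, 20 singletons), `"ms"`, `"lesk"`, `"F-Ic4"`,
#' `"F-Ic2"`, `"F-IIIc4"`, `"F-Vc4"`. The published `F-Vc4` grouping
#' omits R and F; they are restored as singleton groups (with a warning)
#' so that the scheme partitions the canonical alphabet.
#'
#' @param name one of the identifiers above.
#' @return an `aa_scheme`.
#' @export
load_builtin_scheme <- function(name) {
  def <- .builtin_schemes[[name]]
  if (is.null(def))
    stop("unknown scheme '", name, "'; valid identifiers: ",
         paste(names(.builtin_schemes), collapse = ", "))
  if (identical(name, "F-Vc4"))
    warning("scheme 'F-Vc4' is published without R and F; ",
            "they are included as singleton groups")
  aa_scheme(name, def$groups, def$window_limit)
}

#' Names of the built-in schemes
#' @return character vector of the nine identifiers.
#' @export
builtin_scheme_names <- function() names(.builtin_schemes)

#' The two published scheme sets
#'
#' Set `"I"` is \{4-Cat, 7-Cat, 20-Cat, ms, lesk, F-Ic4\}; set `"II"`
#' extends it with \{F-Ic2, F-IIIc4, F-Vc4\}. With one kernel per
#' window size up to each scheme's limit, set I yields 25 kernel
#' components and set II yields 34.
#'
#' @param variant `"I"` or `"II"`.
#' @return ordered list of `aa_scheme` objects.
#' @export
scheme_set <- function(variant = c("I", "II")) {
  if (!is.character(variant) || !variant[1] %in% c("I", "II"))
    stop("variant must be \"I\" or \"II\"")
  variant <- variant[1]
  names_I <- c("4-Cat", "7-Cat", "20-Cat", "ms", "lesk", "F-Ic4")
  names_II <- c(names_I, "F-Ic2", "F-IIIc4", "F-Vc4")
  nm <- if (variant == "I") names_I else names_II
  lapply(nm, function(n) suppressWarnings(load_builtin_scheme(n)))
}

#' Recode a protein sequence over a reduced alphabet
#'
#' Each residue is replaced by the index (1-based) of the scheme group
#' containing it. Residues outside every group — ambiguity codes such as
#' B, Z, X, J, U, O, or any non-alphabet character — are kept in place
#' as `NA` and recorded in `invalid_positions`; downstream k-mer
#' counting skips windows that overlap them rather than fabricating a
#' residue identity.
#'
#' @param seq a single non-empty protein sequence string (case
#'   insensitive).
#' @param scheme an `aa_scheme`.
#' @param id optional sequence identifier carried along.
#' @return an object of class `reduced_seq`: list with `source_id`,
#'   `symbols` (integer group indices, `NA` at invalid positions),
#'   `invalid_positions`, `scheme_name`, `alphabet_size`.
#' @export
reduce_sequence <- function(seq, scheme, id = NA_character_) {
  stopifnot(is(scheme, "aa_scheme"))
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("seq must be a single non-empty string")
  residues <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  symbols <- unname(scheme$lookup[residues])
  structure(
    list(source_id = id,
         symbols = symbols,
         invalid_positions = which(is.na(symbols)),
         scheme_name = scheme$name,
         alphabet_size = scheme$alphabet_size),
    class = "reduced_seq")
}

#' Recode many sequences at once
#'
#' @param seqs character vector of sequences; names are used as IDs.
#' @param scheme an `aa_scheme`.
#' @return list of `reduced_seq`, names preserved.
#' @export
reduce_sequences <- function(seqs, scheme) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  out <- mapply(function(s, i) reduce_sequence(s, scheme, id = i),
                seqs, ids, SIMPLIFY = FALSE)
  names(out) <- ids
  out
}

#' Read a user-defined scheme from a text file
#'
#' Format: line 1 is `<name>TAB<window_limit>`; each subsequent
#' non-empty line is one residue group (uppercase one-letter codes,
#' concatenated). The scheme must pass [validate_scheme()].
#'
#' @param path file path.
#' @return an `aa_scheme`.
#' @export
read_scheme_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("scheme file needs a header line and at least one group: ", path)
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 2L)
    stop("scheme file header must be '<name>\\t<window_limit>': ", path)
  wl <- suppressWarnings(as.integer(hdr[[2]]))
  if (is.na(wl)) stop("window limit is not an integer: ", hdr[[2]])
  aa_scheme(hdr[[1]], lines[-1], wl)
}
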