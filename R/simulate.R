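#' Configuration for the synthetic labeled-sequence generator
#'
#' The generator emulates the statistical structure the spectrum kernel
#' exploits: class membership is carried by short conserved motifs whose
#' k-mer occurrence counts separate the classes, on top of an i.i.d.
#' background. It does not emulate real subnuclear sequence statistics,
#' homology or phylogenetic structure.
#'
#' @param n_classes number of classes (>= 2).
#' @param per_class_sizes integer vector of class sizes (imbalance
#'   allowed).
#' @param length_range integer `(min, max)` residue lengths; sequence
#'   lengths are uniform on this range.
#' @param background residue sampling distribution: `"uniform"`
#'   (default; maximizes sensitivity of tests to the planted signal),
#'   `"natural"` (Swiss-Prot-like residue frequencies), or a named
#'   numeric vector over the 20 canonical residues.
#' @param motifs_per_class list (one element per class) of
#'   `list(motif = <string>, rate = <plantings per 100 residues>)`;
#'   `NULL` (default) draws one random 8-residue motif per class from
#'   the seed at rate 1 per 100 residues; `list()` plants nothing
#'   (null data: labels independent of content).
#' @param mutation_rate per-position probability that a planted motif
#'   residue is substituted by a random different residue.
#' @param ambiguity_rate per-position probability of emitting an `X`
#'   (applied after planting).
#' @param seed integer seed; generation is fully deterministic given
#'   the config.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_classes = 2, per_class_sizes = c(50, 50),
                             length_range = c(80, 600),
                             background = "uniform",
                             motifs_per_class = NULL,
                             mutation_rate = 0, ambiguity_rate = 0,
                             seed = 1) {
  n_classes <- as.integer(n_classes)
  per_class_sizes <- as.integer(per_class_sizes)
  stopifnot(n_classes >= 2, length(per_class_sizes) == n_classes,
            all(per_class_sizes >= 1),
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2],
            mutation_rate >= 0, mutation_rate <= 1,
             ambiguity_rate >= 0, ambiguity_rate <= 1)
  structure(list(n_classes = n_classes, per_class_sizes = per_class_sizes,
                 length_range = as.integer(length_range),
                 background = background,
                 motifs_per_class = motifs_per_class,
                 mutation_rate = mutation_rate,
                 ambiguity_rate = ambiguity_rate, seed = as.integer(seed)),
            class = "generator_config")
}

# Swiss-Prot-like background residue frequencies (renormalized over the
# 20 canonical residues).
.natural_freqs <- c(
  A = 0.0825, C = 0.0138, D = 0.0546, E = 0.0672, F = 0.0386, G = 0.0707,
  H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0965, M = 0.0241, N = 0.0406,
  P = 0.0474, Q = 0.0393, R = 0.0553, S = 0.0665, T = 0.0536, V = 0.0686,
  W = 0.0110, Y = 0.0292)

.background_probs <- function(background) {
  if (is.character(background) && length(background) == 1L) {
    if (background == "uniform")
      return(stats::setNames(rep(1 / 20, 20), CANONICAL_RESIDUES))
    if (background == "natural")
      return(.natural_freqs[CANONICAL_RESIDUES] /
               sum(.natural_freqs[CANONICAL_RESIDUES]))
    stop("unknown background preset '", background, "'")
  }
  stopifnot(is.numeric(background),
            setequal(names(background), CANONICAL_RESIDUES))
  background[CANONICAL_RESIDUES] / sum(background)
}

.random_motif <- function(len = 8L)
  paste(sample(CANONICAL_RESIDUES, len, replace = TRUE), collapse = "")

#' Generate a labeled synthetic protein dataset
#'
#' Sequences are drawn i.i.d. from the background distribution; for a
#' class-c sequence of length L, a Poisson(rate/100 * L) number of
#' copies of each class-c motif is planted left-to-right at random
#' non-overlapping positions, each planted residue independently
#' mutated with probability `mutation_rate`. Positions then flip to the
#' ambiguity code `X` with probability `ambiguity_rate`. Output is
#' byte-identical for a fixed config (including the seed).
#'
#' @param config a [generator_config()].
#' @return list with `sequences` (named character vector, IDs
#'   `seq0001`...), `labels` (named character vector aligned to
#'   `sequences`, classes `"C1"`...), and `motifs` (the per-class motif
#'   list actually used).
#' @export
generate_dataset <- function(config) {
  stopifnot(is(config, "generator_config"))
  probs <- .background_probs(config$background)
  .with_seed(config$seed, {
    motifs <- config$motifs_per_class
    if (is.null(motifs))
      motifs <- lapply(seq_len(config$n_classes), function(i)
        list(motif = .random_motif(8L), rate = 1))
    if (length(motifs) > 0 && length(motifs) != config$n_classes)
      stop("motifs_per_class must have one element per class (or be empty)")
    for (m in motifs)
      if (nchar(m$motif) > config$length_range[1])
        stop("motif '", m$motif, "' is longer than the minimum sequence ",
             "length ", config$length_range[1])
    n_total <- sum(config$per_class_sizes)
    ids <- sprintf("seq%04d", seq_len(n_total))
    labels <- rep(paste0("C", seq_len(config$n_classes)),
                  times = config$per_class_sizes)
    sequences <- character(n_total)
    for (i in seq_len(n_total)) {
      L <- sample(config$length_range[1]:config$length_range[2], 1L)
      res <- sample(CANONICAL_RESIDUES, L, replace = TRUE, prob = probs)
      if (length(motifs) > 0) {
        cls <- match(labels[i], paste0("C", seq_len(config$n_classes)))
        m <- motifs[[cls]]
        mres <- strsplit(m$motif, "", fixed = TRUE)[[1]]
        w <- length(mres)
        # every class sequence carries its motif at least once; the
        # rate controls additional Poisson-distributed occurrences
        n_copies <- max(1L, stats::rpois(1L, m$rate / 100 * L))
        free <- rep(TRUE, L)  # start positions still available
        for (cp in seq_len(n_copies)) {
          ok <- which(free[seq_len(L - w + 1L)])
          ok <- ok[vapply(ok, function(p) all(free[p:(p + w - 1L)]),
                          logical(1))]
          if (length(ok) == 0L) break
          p <- ok[sample.int(length(ok), 1L)]
          planted <- mres
          mut <- stats::runif(w) < config$mutation_rate
          if (any(mut))
            planted[mut] <- vapply(which(mut), function(j)
              sample(setdiff(CANONICAL_RESIDUES, mres[j]), 1L), character(1))
          res[p:(p + w - 1L)] <- planted
          free[p:(p + w - 1L)] <- FALSE
        }
      }
      if (config$ambiguity_rate > 0) {
        amb <- stats::runif(L) < config$ambiguity_rate
        res[amb] <- "X"
      }
      sequences[i] <- paste(res, collapse = "")
    }
    list(sequences = stats::setNames(sequences, ids),
         labels = stats::setNames(labels, ids),
         motifs = motifs)
  })
}

#' Generator profiles mirroring the benchmark dataset shapes
#'
#' `"nucploc-like"`: 9 classes with sizes 99, 22, 61, 29, 79, 67, 307,
#' 37, 13 (714 sequences total). `"lei-like"`: 6 classes with sizes 38,
#' 55, 56, 61, 75, 219 (504 total). Only the class counts and size
#' imbalance are mirrored; the sequence content is synthetic
#' planted-motif data.
#'
#' @param name `"nucploc-like"` or `"lei-like"`.
#' @param ... overrides passed on to [generator_config()] (e.g.
#'   `mutation_rate`, `seed`, `motifs_per_class`).
#' @return a `generator_config`.
#' @export
benchmark_profile <- function(name = c("nucploc-like", "lei-like"), ...) {
  if (!is.character(name) || !name[1] %in% c("nucploc-like", "lei-like"))
    stop("unknown profile; valid names: nucploc-like, lei-like")
  sizes <- switch(name[1],
                  "nucploc-like" = c(99L, 22L, 61L, 29L, 79L, 67L, 307L,
                                     37L, 13L),
                  "lei-like" = c(38L, 55L, 56L, 61L, 75L, 219L))
  args <- list(n_classes = length(sizes), per_class_sizes = sizes)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}
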