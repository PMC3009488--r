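s20 <- load_builtin_scheme("20-Cat")

test_that("count_kmers slides a unit-step window over valid symbols", {
  v <- count_kmers(reduce_sequence("AAAA", s20), 2)
  expect_equal(v$n_valid_kmers, 3)
  expect_equal(v$counts, 3L)

  v <- count_kmers(reduce_sequence("AGAG", s20), 2)
  expect_equal(sort(v$counts, decreasing = TRUE), c(2L, 1L))  # AG x2, GA x1
  expect_equal(v$n_valid_kmers, 3)

  set.seed(5)
  v <- count_kmers(reduce_sequence(random_protein(30), s20), 3)
  expect_equal(v$n_valid_kmers, 28)  # L - k + 1

  expect_equal(count_kmers(reduce_sequence("AC", s20), 5)$n_valid_kmers, 0)
  expect_error(count_kmers(reduce_sequence("AC", s20), 0), "positive")
})

test_that("windows overlapping an invalid residue contribute nothing", {
  ms <- load_builtin_scheme("ms")
  # one X at position 4 of 9 kills k windows covering it
  v_clean <- count_kmers(reduce_sequence("AAAAAAAAA", ms), 3)
  v_hole <- count_kmers(reduce_sequence("AAAXAAAAA", ms), 3)
  expect_equal(v_clean$n_valid_kmers - v_hole$n_valid_kmers, 3)
  # count conservation: at most k windows lost per invalid position
  set.seed(8)
  for (i in 1:20) {
    seq <- random_protein(40, c(CANONICAL_RESIDUES, "X"))
    red <- reduce_sequence(seq, ms)
    k <- sample(1:4, 1)
    v <- count_kmers(red, k)
    lost <- (nchar(seq) - k + 1) - v$n_valid_kmers
    expect_gte(lost, 0)
    expect_lte(lost, k * length(red$invalid_positions))
  }
})

test_that("spectrum counts equal dense enumeration on random inputs", {
  set.seed(21)
  schemes <- lapply(c("4-Cat", "lesk", "F-Ic2"), function(n)
    suppressWarnings(load_builtin_scheme(n)))
  for (scheme in schemes) {
    for (rep in 1:5) {
      seq <- random_protein(sample(10:60, 1), c(CANONICAL_RESIDUES, "X"))
      k <- sample(1:3, 1)
      v <- count_kmers(reduce_sequence(seq, scheme), k)
      dense <- dense_counts(seq, scheme, k)
      expect_equal(v$n_valid_kmers, sum(dense))
      sparse_dense <- numeric(scheme$alphabet_size^k)
      sparse_dense[v$kmer_ids + 1] <- v$counts
      expect_equal(sparse_dense, dense)
    }
  }
})

test_that("inner product and squared distance follow the count algebra", {
  u <- count_kmers(reduce_sequence("AGAG", s20), 2)
  v <- count_kmers(reduce_sequence("GAGA", s20), 2)
  expect_equal(spectrum_inner_product(u, v), 4)       # 2*1 + 1*2
  expect_equal(spectrum_inner_product(u, u), sum(u$counts^2))
  expect_equal(squared_spectrum_distance(u, u, "raw"), 0)
  expect_equal(squared_spectrum_distance(u, v, "raw"), 2)  # 5 - 8 + 5

  empty <- count_kmers(reduce_sequence("A", s20), 2)
  expect_equal(spectrum_inner_product(u, empty), 0)
  # disjoint supports: cross term vanishes
  w <- count_kmers(reduce_sequence("CCCC", s20), 2)
  expect_equal(squared_spectrum_distance(u, w, "raw"),
               sum(u$counts^2) + sum(w$counts^2))

  k3 <- count_kmers(reduce_sequence("AGAG", s20), 3)
  expect_error(spectrum_inner_product(u, k3), "window sizes")
  ms <- count_kmers(reduce_sequence("AGAG", load_builtin_scheme("ms")), 2)
  expect_error(spectrum_inner_product(u, ms), "different schemes")
})

test_that("sparse Gaussian kernels match the dense oracle", {
  set.seed(33)
  for (nm in builtin_scheme_names()) {
    scheme <- suppressWarnings(load_builtin_scheme(nm))
    seqs <- replicate(6, random_protein(sample(20:60, 1)))
    k <- sample(1:min(3, scheme$window_limit), 1)
    gamma <- stats::runif(1, 0.05, 2)
    for (nrm in c("l2", "frequency", "raw")) {
      K <- gaussian_kernel_matrix(reduce_sequences(seqs, scheme), k,
                                  gamma = gamma, normalization = nrm)
      expect_equal(unclass(K), dense_gaussian_kernel(seqs, scheme, k, gamma, nrm),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("every single-component kernel is symmetric PSD with unit diagonal", {
  set.seed(7)
  seqs <- replicate(15, random_protein(sample(30:80, 1)))
  for (nm in c("4-Cat", "20-Cat", "F-Vc4")) {
    scheme <- suppressWarnings(load_builtin_scheme(nm))
    K <- gaussian_kernel_matrix(reduce_sequences(seqs, scheme),
                                k = min(2, scheme$window_limit))
    expect_equal(unname(diag(K)), rep(1, 15))
    chk <- check_kernel(K)
    expect_true(chk$symmetric)
    expect_gte(chk$min_eigenvalue, -1e-8 * max(diag(K)))
  }
})

test_that("gamma -> 0 drives all entries to 1", {
  set.seed(2)
  seqs <- replicate(4, random_protein(40))
  K <- gaussian_kernel_matrix(reduce_sequences(seqs, s20), 2, gamma = 1e-12)
  expect_equal(unclass(K), matrix(1, 4, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("kernel rows/columns permute with the input order", {
  set.seed(13)
  seqs <- stats::setNames(replicate(8, random_protein(50)), paste0("s", 1:8))
  red <- reduce_sequences(seqs, s20)
  K <- gaussian_kernel_matrix(red, 2)
  perm <- sample(8)
  Kp <- gaussian_kernel_matrix(red[perm], 2)
  expect_equal(unclass(Kp), unclass(K)[perm, perm], ignore_attr = TRUE)
})

test_that("cross-kernel blocks agree with the square matrix", {
  set.seed(17)
  seqs <- stats::setNames(replicate(9, random_protein(45)), paste0("q", 1:9))
  red <- reduce_sequences(seqs, load_builtin_scheme("ms"))
  K <- gaussian_kernel_matrix(red, 3, gamma = 0.7)
  Kc <- cross_kernel_matrix(red[1:4], red[5:9], 3, gamma = 0.7)
  expect_equal(Kc, unclass(K)[1:4, 5:9], ignore_attr = TRUE,
               tolerance = 1e-12)
  # identical test and train sequence: kernel value exactly 1
  Kid <- cross_kernel_matrix(red[3], red[c(3, 7)], 3, gamma = 0.7)
  expect_equal(Kid[1, 1], 1)
  expect_error(cross_kernel_matrix(list(), red, 2), "empty")
})

test_that("sequences shorter than k yield zero vectors with kernel 1", {
  red <- reduce_sequences(c(a = "ACD", b = "MKVLW", c = "AC"), s20)
  expect_warning(K <- gaussian_kernel_matrix(red, 4), "empty")
  expect_equal(unclass(K)[1, 3], 1)  # two zero spectra are identical
})

test_that("k above the scheme window limit warns but computes", {
  scheme <- load_builtin_scheme("20-Cat")
  red <- reduce_sequences(c(x = "MKVLWAAC", y = "MKVLWAAD"), scheme)
  expect_warning(K <- gaussian_kernel_matrix(red, 4, scheme = scheme),
                 "window limit")
  expect_equal(dim(K), c(2L, 2L))
})

test_that("kernel matrices round-trip exactly through the TSV format", {
  set.seed(3)
  seqs <- stats::setNames(replicate(5, random_protein(30)), paste0("r", 1:5))
  K <- gaussian_kernel_matrix(reduce_sequences(seqs, s20), 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel_tsv(K, path)
  K2 <- read_kernel_tsv(path)
  expect_identical(unclass(K2)[, ], unclass(K)[, ])
  expect_equal(attr(K2, "meta")$gamma, attr(K, "meta")$gamma)
  expect_equal(attr(K2, "meta")$scheme, "20-Cat")
})
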