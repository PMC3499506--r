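#' Friedman benchmark response function
#'
#' The standard five-variable synthetic regression benchmark
#' `10 sin(pi x1 x2) + 20 (x3 - 0.5)^2 + 10 x4 + 5 x5` on the unit
#' hypercube: two linear terms (x4, x5), one quadratic (x3) and one
#' interaction through a sine (x1, x2). Deterministic; noise is added by
#' [generate_friedman()].
#'
#' @param x numeric vector of 5 values in `[0, 1]`, or a matrix with 5+
#'   columns (only the first five are used, row-wise).
#' @return Noiseless response value(s).
#' @export
friedman_response <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 5) .stop_arg("need at least 5 feature columns")
    X <- x[, 1:5, drop = FALSE]
  } else {
    if (length(x) != 5) .stop_arg("x must have exactly 5 values")
    X <- matrix(x, nrow = 1)
  }
  if (any(X < 0 | X > 1)) .stop_arg("Friedman inputs must lie in [0, 1]")
  10 * sin(pi * X[, 1] * X[, 2]) + 20 * (X[, 3] - 0.5)^2 + 10 * X[, 4] + 5 * X[, 5]
}

#' Generate a seeded Friedman-function dataset
#'
#' Samples `m_total` features i.i.d. uniform on `[0, 1]`; the response is
#' the Friedman function of the first five features plus Gaussian noise
#' of standard deviation `sigma`. Features beyond the fifth are pure
#' nuisance with no influence on the response, which makes the generator
#' suitable for studying feature selection and the effect of dataset
#' size, dimensionality, and noise on confidence estimation.
#'
#' @param n number of instances.
#' @param m_total total number of features (>= 5).
#' @param sigma response noise standard deviation (>= 0).
#' @param seed integer seed; identical arguments give an identical
#'   dataset.
#' @return A [conf_dataset()].
#' @export
generate_friedman <- function(n, m_total = 10, sigma = 1, seed = 1) {
  if (!.is_count(n) || n < 1) .stop_arg("n must be a positive integer")
  if (!.is_count(m_total) || m_total < 5) .stop_arg("m_total must be an integer >= 5")
  if (!is.numeric(sigma) || sigma < 0) .stop_arg("sigma must be >= 0")
  with_seed(seed, {
    X <- matrix(stats::runif(n * m_total), nrow = n, ncol = m_total)
    y <- friedman_response(X) + stats::rnorm(n, sd = sigma)
    conf_dataset(X, y)
  })
}

# ---- 9-mer peptide encoding --------------------------------------------

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Amino-acid physicochemical property table
#'
#' The six per-residue values appended to each one-hot block by
#' [encode_peptides()]: Kyte-Doolittle hydrophobicity, Hopp-Woods
#' hydrophilicity, net side-chain charge at pH 7 (histidine counted as
#' +0.1), Eisenberg consensus hydrophobicity, a polar-residue flag and an
#' aromatic-residue flag. This is a bundled stand-in assembled from
#' standard published scales; pass your own 6-column table to
#' [encode_peptides()] to override it.
#'
#' @return A 20 x 6 numeric matrix, rows named by amino acid in
#'   alphabetical one-letter order (ACDEFGHIKLMNPQRSTVWY).
#' @export
aa_property_table <- function() {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  hw <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
          I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
          R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  charge <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0,
              K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
              T = 0, V = 0, W = 0, Y = 0)
  eis <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
           H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
           P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
           W = 0.81, Y = 0.26)
  polar <- c(A = 0, C = 1, D = 1, E = 1, F = 0, G = 0, H = 1, I = 0, K = 1,
             L = 0, M = 0, N = 1, P = 0, Q = 1, R = 1, S = 1, T = 1, V = 0,
             W = 0, Y = 1)
  arom <- c(A = 0, C = 0, D = 0, E = 0, F = 1, G = 0, H = 1, I = 0, K = 0,
            L = 0, M = 0, N = 0, P = 0, Q = 0, R = 0, S = 0, T = 0, V = 0,
            W = 1, Y = 1)
  M <- cbind(kd = kd[.AA_ALPHABET], hw = hw[.AA_ALPHABET],
             charge = charge[.AA_ALPHABET], eisenberg = eis[.AA_ALPHABET],
             polar = polar[.AA_ALPHABET], aromatic = arom[.AA_ALPHABET])
  rownames(M) <- .AA_ALPHABET
  M
}

#' Encode 9-mer peptides as a numeric dataset
#'
#' Position-wise encoding for MHC class I binding regression: each of the
#' nine positions contributes 20 one-hot features (alphabetical amino-acid
#' order ACDEFGHIKLMNPQRSTVWY) plus six physicochemical values (see
#' [aa_property_table()]), giving 9 x 26 = 234 features.
#'
#' @param peptides character vector of 9-letter amino-acid strings.
#' @param responses numeric responses (e.g. binding affinities), one per
#'   peptide.
#' @param properties optional 20 x 6 numeric matrix (rows in alphabetical
#'   amino-acid order) overriding the bundled property table.
#' @return A [conf_dataset()] with 234 features.
#' @export
encode_peptides <- function(peptides, responses, properties = NULL) {
  if (length(peptides) != length(responses))
    .stop_arg("peptides and responses lengths differ")
  if (is.null(properties)) properties <- aa_property_table()
  properties <- as.matrix(properties)
  if (nrow(properties) != 20 || ncol(properties) != 6)
    .stop_arg("properties must be a 20 x 6 matrix")
  if (is.null(colnames(properties)))
    colnames(properties) <- paste0("prop", 1:6)
  chars <- strsplit(toupper(peptides), "")
  for (i in seq_along(chars)) {
    if (length(chars[[i]]) != 9)
      .stop_arg("peptide ", i, " has length ", length(chars[[i]]), "; expected 9")
    bad <- which(!chars[[i]] %in% .AA_ALPHABET)
    if (length(bad))
      .stop_arg("peptide ", i, ": unknown letter '", chars[[i]][bad[1]],
                "' at position ", bad[1])
  }
  aa_idx <- lapply(chars, match, .AA_ALPHABET)
  n <- length(peptides)
  X <- matrix(0, nrow = n, ncol = 9 * 26)
  for (pos in 1:9) {
    off <- (pos - 1) * 26
    idx <- vapply(aa_idx, `[[`, 0L, pos)
    X[cbind(seq_len(n), off + idx)] <- 1
    X[, off + 20 + (1:6)] <- properties[idx, , drop = FALSE]
  }
  names_block <- c(paste0("aa", .AA_ALPHABET), colnames(properties))
  colnames(X) <- as.vector(vapply(1:9, function(p) paste0("p", p, "_", names_block),
                                  character(26)))
  conf_dataset(X, responses)
}

#' Read peptides with responses from a text file
#'
#' Accepts a two-column TSV (peptide, response; no header needed), a
#' plain list of one 9-mer per line (then `responses` must be supplied),
#' or a FASTA file whose description lines carry the response after an
#' `affinity=` token.
#'
#' @param path input file.
#' @param responses optional numeric vector for the plain-list format.
#' @param format `"auto"`, `"tsv"`, `"plain"` or `"fasta"`.
#' @return A list with `peptides` (character) and `responses` (numeric).
#' @export
read_peptides <- function(path, responses = NULL, format = c("auto", "tsv", "plain", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) "fasta"
    else {
      first <- readLines(path, n = 1)
      if (startsWith(first, ">")) "fasta"
      else if (grepl("\t", first)) "tsv" else "plain"
    }
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      .stop_arg("reading FASTA peptides requires the Biostrings package")
    seqs <- Biostrings::readAAStringSet(path)
    desc <- names(seqs)
    m <- regmatches(desc, regexpr("affinity=[-0-9.eE+]+", desc))
    if (length(m) != length(seqs))
      .stop_arg("every FASTA description must carry an 'affinity=' token")
    list(peptides = unname(as.character(seqs)),
         responses = as.numeric(sub("affinity=", "", m)))
  } else if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (is.character(df[[1]]) && tolower(df[[1]][1]) %in% c("peptide", "sequence"))
      df <- df[-1, , drop = FALSE]
    list(peptides = as.character(df[[1]]), responses = as.numeric(df[[2]]))
  } else {
    peps <- readLines(path)
    peps <- peps[nzchar(peps)]
    if (is.null(responses)) .stop_arg("plain peptide lists need a responses vector")
    list(peptides = peps, responses = responses)
  }
}
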