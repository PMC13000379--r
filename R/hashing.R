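#' 32-bit FNV-1a string hash
#'
#' A pinned, library-independent implementation of the Fowler–Noll–Vo 1a
#' hash (offset basis 2166136261, prime 16777619, modulo 2^32) over the
#' UTF-8 bytes of each string. All arithmetic stays below 2^53, so values
#' are exact in doubles and identical across platforms and processes.
#'
#' @param x Character vector.
#' @return Numeric vector of unsigned 32-bit hash values.
#' @examples
#' fnv1a32(c("I10.9", "E11.9"))
#' @export
fnv1a32 <- function(x) {
  stopifnot(is.character(x))
  prime <- 16777619
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 2166136261
    for (b in bytes) {
      lo8 <- h %% 256
      h <- h - lo8 + bitwXor(as.integer(lo8), b)
      lo <- h %% 65536
      hi <- h %/% 65536
      h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Column index (1-based) and sign for each code under the signed hashing
# trick: index from FNV-1a of the code, sign from bit 16 of a second hash
# of the code with a fixed "#s" suffix. Bit 0 is unusable as a sign bit:
# the parity of an FNV-1a hash is just the XOR of its input byte parities,
# which would tie the sign deterministically to the index.
hash_index_sign <- function(codes, n_bits) {
  idx <- (fnv1a32(codes) %% 2^n_bits) + 1
  sgn <- ifelse((fnv1a32(paste0(codes, "#s")) %/% 65536) %% 2 == 0, 1, -1)
  list(index = as.integer(idx), sign = as.numeric(sgn))
}

#' Signed feature hashing of diagnosis-code multisets
#'
#' Maps each patient's multiset of (non-defining) diagnosis codes into a
#' sparse vector of dimension `2^n_bits` (262,144 columns at the default 18
#' bits). Each code occurrence increments the entry at
#' `FNV1a(code) mod 2^n_bits` by +1 or -1 according to a stable bit (bit 16)
#' of a second hash of the code with a fixed `"#s"` suffix, so colliding
#' codes cancel in expectation. Deterministic across processes and runs.
#'
#' @param code_multisets Named list: one character vector of codes (with
#'   repeats) per patient.
#' @param n_bits Hash width exponent, in \[8, 30\].
#' @return A `dgCMatrix` with one row per patient (rownames = patient ids)
#'   and exactly `2^n_bits` columns.
#' @export
hash_features <- function(code_multisets, n_bits = 18L) {
  if (n_bits < 8 || n_bits > 30) stop("n_bits must lie in [8, 30]", call. = FALSE)
  stopifnot(is.list(code_multisets))
  n <- length(code_multisets)
  d <- as.integer(2^n_bits)
  all_codes <- unlist(code_multisets, use.names = FALSE)
  if (length(all_codes) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, d),
                                dimnames = list(names(code_multisets), NULL)))
  }
  uniq <- unique(all_codes)
  hs <- hash_index_sign(uniq, n_bits)
  code_id <- match(all_codes, uniq)
  row_id <- rep(seq_len(n), lengths(code_multisets))
  Matrix::sparseMatrix(
    i = row_id, j = hs$index[code_id], x = hs$sign[code_id],
    dims = c(n, d), dimnames = list(names(code_multisets), NULL)
  )
}

#' Exclude label-defining codes from a feature multiset
#'
#' The leakage guard: every code matching any label specification is
#' removed before hashing, so no defining code can contribute to the
#' feature space; all other codes pass through untouched.
#'
#' @param event_codes Character vector (multiset) of codes.
#' @param label_specs List of [code_spec()]s (default the three modelled
#'   conditions).
#' @return The filtered multiset.
#' @examples
#' exclude_defining_codes(c("I10.9", "J45.9", "E11.9"))
#' @export
exclude_defining_codes <- function(event_codes, label_specs = default_label_specs()) {
  if (length(event_codes) == 0L) return(event_codes)
  event_codes[!matches_any_spec(event_codes, lapply(label_specs, code_spec))]
}

#' Per-patient code multisets with defining codes excluded
#'
#' The feature-pipeline input surface: splits a deduplicated event table
#' into per-patient diagnosis-code multisets and applies
#' [exclude_defining_codes()]. Auditing this function's output for defining
#' codes certifies the leakage guard.
#'
#' @param table Deduplicated encounter table.
#' @param exclude Label specs to exclude (`NULL` to keep everything).
#' @return Named list of character vectors, one per patient (sorted ids).
#' @export
patient_code_multisets <- function(table, exclude = default_label_specs()) {
  tab <- data.table::as.data.table(table)
  sets <- split(tab$dx_code, tab$patient_id)
  if (!is.null(exclude)) sets <- lapply(sets, exclude_defining_codes, label_specs = exclude)
  sets
}

#' Patient-level binary label matrix
#'
#' A patient carries a label iff at least one of its events matches the
#' label's specification.
#'
#' @param table Deduplicated encounter table.
#' @param label_specs Named list of [code_spec()]s.
#' @return Integer matrix, patients (sorted ids) by labels.
#' @export
build_label_matrix <- function(table, label_specs = default_label_specs()) {
  tab <- data.table::as.data.table(table)
  specs <- lapply(label_specs, code_spec)
  ids <- sort(unique(tab$patient_id))
  Y <- matrix(0L, nrow = length(ids), ncol = length(specs),
              dimnames = list(ids, names(specs)))
  for (j in seq_along(specs)) {
    carriers <- unique(tab$patient_id[match_codes(tab$dx_code, specs[[j]])])
    Y[match(carriers, ids), j] <- 1L
  }
  Y
}

#' Patient-level train/validation/test split
#'
#' A seeded shuffle followed by contiguous allocation at the stated
#' fractions (largest-remainder rounding, so counts are within one patient
#' of exact). Assignment is at patient level: all rows of a patient share a
#' split.
#'
#' @param patient_ids Distinct patient identifiers.
#' @param fractions Named fractions summing to 1
#'   (default `c(train = .65, validation = .15, test = .20)`).
#' @param seed Integer seed (default 42).
#' @return Named factor mapping each patient id to its split.
#' @export
split_patients <- function(patient_ids,
                           fractions = c(train = 0.65, validation = 0.15, test = 0.20),
                           seed = 42L) {
  if (anyDuplicated(patient_ids)) stop("patient_ids must be distinct", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  n <- length(patient_ids)
  base <- floor(fractions * n)
  rem <- fractions * n - base
  short <- n - sum(base)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1L
  }
  shuffled <- with_seed(seed, sample(patient_ids))
  assignment <- factor(rep(names(fractions), base), levels = names(fractions))
  names(assignment) <- shuffled
  assignment[match(patient_ids, names(assignment))]
}

#' Positive-class weights from training labels
#'
#' The boosted-tree imbalance weight per label:
#' `#negatives / #positives` on the training split.
#'
#' @param labels_train Binary label matrix (patients x labels) or vector.
#' @return Named numeric weights.
#' @export
pos_weight <- function(labels_train) {
  Y <- as.matrix(labels_train)
  npos <- colSums(Y == 1)
  nneg <- colSums(Y == 0)
  if (any(npos == 0)) {
    stop("label(s) with zero positives in training data: ",
         paste(colnames(Y)[npos == 0], collapse = ", "), call. = FALSE)
  }
  setNames(nneg / npos, colnames(Y))
}
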