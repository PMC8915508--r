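#' Jaccard similarity between two diagnosis sets
#'
#' `|intersection| / |union|` over the point-of-admission diagnosis sets of
#' two admissions. Undefined (error) when both sets are empty.
#'
#' @param a,b Character vectors of diagnosis codes.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' jaccard_similarity(c("I10", "E11"), c("I10", "N18")) # 1/3
jaccard_similarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) abort("Jaccard similarity undefined for two empty sets")
  length(intersect(a, b)) / u
}

block_keys <- function(records) {
  paste(records$sex, as.character(age_group(records$age)), sep = "/")
}

#' Build the blocked patient-similarity index over training admissions
#'
#' Admissions are partitioned into sex x five-year age-band blocks (see
#' [age_group()]); similarity is only ever evaluated within a block. Each
#' block stores a sparse binary matrix of the admissions' chronic
#' point-of-admission diagnosis sets for exact top-k Jaccard retrieval via
#' sparse intersection counts.
#'
#' @param train_records Admission-record tibble (training rows only; each
#'   must have at least one chronic PoA diagnosis).
#' @param catalog [chronic_catalog()] restricting the diagnosis sets.
#' @param backend Only `"exact"` is provided: it returns the true top-k.
#' @return An object of class `similarity_index`.
#' @export
build_similarity_index <- function(train_records, catalog, backend = "exact") {
  if (!identical(backend, "exact")) {
    abort("only the exact backend is available; it returns the true Jaccard top-k")
  }
  if (nrow(train_records) == 0) abort("empty training set")
  sets <- diagnosis_sets(train_records, poa_only = TRUE, catalog = catalog)
  if (any(lengths(sets) == 0)) {
    abort("every indexed admission needs >= 1 chronic PoA diagnosis (run the inclusion filter first)")
  }
  codes <- sort(unique(unlist(sets)))
  keys <- block_keys(train_records)
  if (anyNA(age_group(train_records$age))) {
    abort("ages below 65 cannot be blocked; apply the inclusion criteria first")
  }
  blocks <- list()
  for (k in unique(keys)) {
    rows <- which(keys == k)
    long_codes <- unlist(sets[rows])
    M <- Matrix::sparseMatrix(
      i = rep(seq_along(rows), lengths(sets[rows])),
      j = match(long_codes, codes),
      x = 1,
      dims = c(length(rows), length(codes))
    )
    blocks[[k]] <- list(
      mat = M,
      set_size = lengths(sets[rows]),
      id = train_records$record_id[rows],
      patient_id = train_records$patient_id[rows],
      los = train_records$los[rows]
    )
  }
  structure(
    list(blocks = blocks, codes = codes, n = nrow(train_records), backend = backend),
    class = "similarity_index"
  )
}

#' @export
print.similarity_index <- function(x, ...) {
  cat("<similarity_index>", x$n, "training admissions in",
    length(x$blocks), "sex/age blocks\n")
  invisible(x)
}

#' Top-k Jaccard neighbours for query admissions
#'
#' For each query admission, returns the `k` most similar training
#' admissions within the query's sex x age-band block, ranked by Jaccard
#' similarity over chronic PoA diagnosis sets. The query's own record id is
#' never returned; with `exclude_same_patient` (default) no neighbour shares
#' the query's `patient_id`, preventing a patient's own past stays from
#' leaking their LOS through the similarity channel. Zero-similarity
#' candidates are dropped (a neighbour sharing no disease carries no
#' information), so lists may be shorter than `k`; ties are broken by
#' ascending record id for reproducibility.
#'
#' @param index A `similarity_index` from [build_similarity_index()].
#' @param records Query admission tibble.
#' @param catalog The same catalog the index was built with.
#' @param k Neighbours per query (default 100).
#' @param exclude_same_patient Drop same-patient training admissions
#'   (default `TRUE`).
#' @return A tibble `query_id`, `rank`, `neighbor_id`, `similarity`,
#'   `neighbor_los`; zero rows for queries with an empty block.
#' @export
query_neighbors <- function(index, records, catalog, k = 100L,
                            exclude_same_patient = TRUE) {
  keys <- block_keys(records)
  sets <- diagnosis_sets(records, poa_only = TRUE, catalog = catalog)
  out <- vector("list", nrow(records))
  oi <- 0L
  for (key in unique(keys)) {
    rows <- which(keys == key)
    block <- index$blocks[[key]]
    if (is.null(block)) next
    qsets <- sets[rows]
    nz <- lengths(qsets) > 0
    rows <- rows[nz]
    qsets <- qsets[nz]
    if (length(rows) == 0) next
    hit <- match(unlist(qsets), index$codes)
    keep <- !is.na(hit)
    Q <- Matrix::sparseMatrix(
      i = rep(seq_along(rows), lengths(qsets))[keep],
      j = hit[keep],
      x = 1,
      dims = c(length(rows), length(index$codes))
    )
    inter <- as.matrix(Matrix::tcrossprod(Q, block$mat))
    qsize <- lengths(qsets)
    sim <- inter / (outer(qsize, block$set_size, `+`) - inter)

    qids <- sims <- nbids <- nblos <- ranks <- vector("list", length(rows))
    for (qi in seq_along(rows)) {
      s <- sim[qi, ]
      qid <- records$record_id[rows[qi]]
      drop <- block$id == qid
      if (exclude_same_patient) {
        drop <- drop | block$patient_id == records$patient_id[rows[qi]]
      }
      s[drop] <- 0
      cand <- which(s > 0)
      if (length(cand) == 0) next
      ord <- head(cand[order(-s[cand], block$id[cand])], k)
      qids[[qi]] <- rep(qid, length(ord))
      ranks[[qi]] <- seq_along(ord)
      nbids[[qi]] <- block$id[ord]
      sims[[qi]] <- s[ord]
      nblos[[qi]] <- block$los[ord]
    }
    oi <- oi + 1L
    out[[oi]] <- tibble(
      query_id = unlist(qids) %||% character(0),
      rank = unlist(ranks) %||% integer(0),
      neighbor_id = unlist(nbids) %||% character(0),
      similarity = unlist(sims) %||% numeric(0),
      neighbor_los = unlist(nblos) %||% numeric(0)
    )
  }
  empty <- tibble(
    query_id = character(), rank = integer(), neighbor_id = character(),
    similarity = numeric(), neighbor_los = numeric()
  )
  if (oi == 0) return(empty)
  bind_rows(c(list(empty), out[seq_len(oi)]))
}
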