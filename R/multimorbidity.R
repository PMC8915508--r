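#' Build the sparse patient-disease matrix
#'
#' One row per distinct patient with at least one catalog chronic diagnosis
#' in the era, one column per catalog code observed in the era; an entry is
#' 1 if any of the patient's era records lists the disease in any diagnosis
#' position (point-of-admission and in-hospital alike; a multimorbidity
#' network should see the full comorbid burden, not just what was coded on
#' arrival).
#'
#' @param records Admission-record tibble (usually post-inclusion).
#' @param catalog [chronic_catalog()] of chronic codes.
#' @param era Optional length-2 date vector restricting admission dates.
#' @return A sparse binary `dgCMatrix` (patients x diseases) with dimnames.
#' @export
build_disease_matrix <- function(records, catalog, era = NULL) {
  x <- records
  if (!is.null(era)) {
    era <- as.Date(era)
    x <- x[x$admission_date >= era[1] & x$admission_date <= era[2], , drop = FALSE]
  }
  sets <- diagnosis_sets(x, poa_only = FALSE, catalog = catalog)
  keep <- lengths(sets) > 0
  x <- x[keep, , drop = FALSE]
  sets <- sets[keep]
  if (nrow(x) == 0) abort("no qualifying records: empty patient-disease matrix")

  long <- tibble(
    patient_id = rep(x$patient_id, lengths(sets)),
    code = unlist(sets)
  ) |> distinct()
  patients <- sort(unique(long$patient_id))
  codes <- sort(unique(long$code))
  M <- Matrix::sparseMatrix(
    i = match(long$patient_id, patients),
    j = match(long$code, codes),
    x = 1,
    dims = c(length(patients), length(codes)),
    dimnames = list(patients, codes)
  )
  methods::as(M, "CsparseMatrix")
}

#' Disease-by-disease co-occurrence counts
#'
#' Computed as the cross product `t(M) %*% M` of the sparse binary
#' patient-disease matrix, so the diagonal holds the per-disease patient
#' counts `C_i` and off-diagonal cells the pair counts `C_ij`.
#'
#' @param M Sparse binary patient-disease matrix from
#'   [build_disease_matrix()].
#' @return A symmetric sparse matrix of integer counts.
#' @export
cooccurrence_counts <- function(M) {
  Matrix::crossprod(M)
}

#' Relative risk of disease co-occurrence
#'
#' `RR = C_ij * N / (C_i * C_j)`: the observed number of patients carrying
#' both diseases relative to the number expected if the two diseases
#' attached independently to the `N` patients.
#'
#' @param c_ij Patients with both diseases.
#' @param c_i,c_j Patients with each disease (must be >= 1).
#' @param n Total patients in the population (>= 1).
#' @return The relative risk; vectorized over its arguments.
#' @export
#' @examples
#' relative_risk(10, 20, 50, 1000) # 10
relative_risk <- function(c_ij, c_i, c_j, n) {
  if (any(c_i < 1) || any(c_j < 1) || any(n < 1)) {
    abort("relative risk undefined: C_i, C_j and N must be >= 1")
  }
  if (any(c_ij > pmin(c_i, c_j))) {
    abort("C_ij cannot exceed min(C_i, C_j)")
  }
  c_ij * n / (c_i * c_j)
}

#' Katz-style confidence interval for a co-occurrence relative risk
#'
#' Multiplicative interval `RR * exp(-z * sigma), RR * exp(z * sigma)` with
#' `z = 2.58` for a nominal 99% level. The dispersion term is
#' `s = 1/C_ij + 1/(C_i C_j) - 1/N - 1/N^2`. `sigma_mode` selects whether
#' `sigma = s` is used directly (`"as_printed"`, the default, matching the
#' formula as commonly printed) or `sigma = sqrt(s)` (`"sqrt"`, the Katz
#' log-scale standard error; `s` is a variance-scale quantity, so this is
#' the statistically calibrated choice and the default for edge retention
#' in [build_mn()]).
#'
#' @param rr Relative risk from [relative_risk()].
#' @param c_ij,c_i,c_j,n Counts as in [relative_risk()]; `c_ij >= 1`.
#' @param z Normal multiplier (default 2.58, i.e. 99%).
#' @param sigma_mode `"as_printed"` or `"sqrt"`.
#' @return A tibble with columns `ci_low`, `ci_high`; vectorized.
#' @export
#' @examples
#' katz_ci(10, 10, 20, 50, 1000) # approx (7.725, 12.944)
katz_ci <- function(rr, c_ij, c_i, c_j, n, z = 2.58,
                    sigma_mode = c("as_printed", "sqrt")) {
  sigma_mode <- match.arg(sigma_mode)
  if (any(c_ij < 1)) abort("CI undefined for C_ij = 0")
  s <- 1 / c_ij + 1 / (c_i * c_j) - 1 / n - 1 / n^2
  sigma <- if (sigma_mode == "sqrt") sqrt(pmax(s, 0)) else s
  tibble(ci_low = rr * exp(-z * sigma), ci_high = rr * exp(z * sigma))
}

#' Build the multimorbidity network
#'
#' Nodes are the diseases of the patient-disease matrix; candidate edges are
#' unordered pairs co-occurring in at least `min_pair_count` patients. Each
#' candidate edge carries `C_ij`, `RR` and the Katz-style CI; retention is
#' governed by `edge_rule`: keep edges whose 99% CI lower bound exceeds 1
#' (`"ci_low_gt_1"`, the default; the conventional significance rule for
#' disease co-occurrence networks), whose point RR exceeds 1 (`"rr_gt_1"`),
#' or all candidates (`"all"`). Edge significance uses `sigma_mode = "sqrt"`
#' by default so the nominal level of the retention test is meaningful; the
#' as-printed variant is available.
#'
#' @param M Sparse patient-disease matrix from [build_disease_matrix()].
#' @param min_pair_count Minimum `C_ij` for a candidate edge (default 1).
#' @param edge_rule Retention rule (see above).
#' @param sigma_mode Passed to [katz_ci()]; default `"sqrt"`.
#' @param z CI multiplier (default 2.58 for 99%).
#' @return An object of class `multimorbidity_network`: list with `nodes`
#'   (tibble `code`, `count`), `edges` (tibble `code_i`, `code_j`, `c_ij`,
#'   `rr`, `ci_low`, `ci_high`), `n_patients`, `n_candidates` and the
#'   construction options.
#' @export
build_mn <- function(M, min_pair_count = 1L,
                     edge_rule = c("ci_low_gt_1", "rr_gt_1", "all"),
                     sigma_mode = c("sqrt", "as_printed"),
                     z = 2.58) {
  edge_rule <- match.arg(edge_rule)
  sigma_mode <- match.arg(sigma_mode)
  counts <- cooccurrence_counts(M)
  n_pat <- nrow(M)
  ci_diag <- Matrix::diag(counts)
  codes <- colnames(M)

  cmat <- methods::as(methods::as(counts, "generalMatrix"), "TsparseMatrix")
  upper <- cmat@i < cmat@j & cmat@x >= min_pair_count
  i <- cmat@i[upper] + 1L
  j <- cmat@j[upper] + 1L
  c_ij <- cmat@x[upper]

  edges <- tibble(
    code_i = codes[i], code_j = codes[j],
    c_ij = as.integer(c_ij),
    rr = relative_risk(c_ij, ci_diag[i], ci_diag[j], n_pat)
  )
  if (nrow(edges) > 0) {
    ci <- katz_ci(edges$rr, c_ij, ci_diag[i], ci_diag[j], n_pat,
      z = z, sigma_mode = sigma_mode
    )
    edges <- bind_cols(edges, ci)
  } else {
    edges$ci_low <- numeric(0)
    edges$ci_high <- numeric(0)
  }
  n_candidates <- nrow(edges)
  edges <- switch(edge_rule,
    ci_low_gt_1 = edges[edges$ci_low > 1, , drop = FALSE],
    rr_gt_1 = edges[edges$rr > 1, , drop = FALSE],
    all = edges
  )

  structure(
    list(
      nodes = tibble(code = codes, count = as.integer(ci_diag)),
      edges = as_tibble(edges),
      n_patients = n_pat,
      n_candidates = n_candidates,
      options = list(
        min_pair_count = min_pair_count, edge_rule = edge_rule,
        sigma_mode = sigma_mode, z = z
      )
    ),
    class = "multimorbidity_network"
  )
}

#' @export
print.multimorbidity_network <- function(x, ...) {
  cat("<multimorbidity_network>\n")
  cat("  ", nrow(x$nodes), "diseases,", nrow(x$edges), "edges (",
    x$options$edge_rule, ", sigma:", x$options$sigma_mode, ")\n")
  cat("  built from", x$n_patients, "patients\n")
  invisible(x)
}

# Weighted adjacency of the MN as a sparse symmetric matrix.
mn_adjacency <- function(mn, weight_mode = c("rr", "binary")) {
  weight_mode <- match.arg(weight_mode)
  codes <- mn$nodes$code
  e <- mn$edges
  w <- if (weight_mode == "rr") e$rr else rep(1, nrow(e))
  Matrix::sparseMatrix(
    i = c(match(e$code_i, codes), match(e$code_j, codes)),
    j = c(match(e$code_j, codes), match(e$code_i, codes)),
    x = c(w, w),
    dims = c(length(codes), length(codes)),
    dimnames = list(codes, codes)
  )
}

# Connected components of a symmetric sparse adjacency via BFS over the
# column pointers; returns an integer membership vector.
components_of <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  Ap <- methods::as(A, "CsparseMatrix")
  nb <- function(v) Ap@i[(Ap@p[v] + 1L):Ap@p[v + 1L]] + 1L
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (Ap@p[v + 1L] > Ap@p[v]) {
        nv <- nb(v)
        new <- nv[is.na(comp[nv])]
        comp[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  comp
}

#' Eigenvector centrality of the multimorbidity network
#'
#' Power iteration on the (RR-weighted by default) adjacency matrix: the
#' score vector is the principal eigenvector, i.e. the fixed point of
#' `A x = lambda x` for the largest eigenvalue. Disconnected graphs are
#' handled per connected component, each component's scores Euclidean-
#' normalized to 1; isolated nodes score 0. The all-ones start vector and
#' enforced non-negativity make the result deterministic.
#'
#' @param mn A `multimorbidity_network` from [build_mn()].
#' @param weight_mode `"rr"` (default) or `"binary"` adjacency.
#' @param tol L1 convergence tolerance between successive normalized
#'   iterates (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return A named numeric vector of non-negative scores, one per node.
#' @export
eigenvector_centrality <- function(mn, weight_mode = c("rr", "binary"),
                                   tol = 1e-10, max_iter = 10000L) {
  weight_mode <- match.arg(weight_mode)
  A <- mn_adjacency(mn, weight_mode)
  n <- nrow(A)
  if (n == 0) abort("empty network")
  comp <- components_of(A)
  scores <- numeric(n)
  deg <- Matrix::rowSums(A != 0)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1 || all(deg[idx] == 0)) next # isolated: score 0
    Ac <- A[idx, idx, drop = FALSE]
    # small diagonal shift: keeps the eigenvectors, separates the dominant
    # eigenvalue on bipartite components (where plain iteration oscillates)
    shift <- 0.05 * max(Matrix::rowSums(abs(Ac)))
    x <- rep(1 / sqrt(length(idx)), length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      x_new <- as.numeric(Ac %*% x) + shift * x
      nrm <- sqrt(sum(x_new^2))
      if (nrm == 0) break
      x_new <- abs(x_new / nrm)
      if (sum(abs(x_new - x)) < tol) {
        x <- x_new
        converged <- TRUE
        break
      }
      x <- x_new
    }
    if (!converged) {
      resid <- as.numeric(Ac %*% x) + shift * x
      resid <- sum(abs(abs(resid / sqrt(sum(resid^2))) - x))
      abort(sprintf(
        "eigenvector centrality did not converge in %d iterations (residual %.3g)",
        max_iter, resid
      ))
    }
    scores[idx] <- x
  }
  setNames(scores, mn$nodes$code)
}

#' Attach eigenvector-centrality scores to the network nodes
#'
#' @inheritParams eigenvector_centrality
#' @return The network with an `evc` column on `nodes`.
#' @export
add_centrality <- function(mn, weight_mode = c("rr", "binary"),
                           tol = 1e-10, max_iter = 10000L) {
  evc <- eigenvector_centrality(mn, weight_mode, tol, max_iter)
  mn$nodes$evc <- unname(evc[mn$nodes$code])
  mn
}

#' Export the multimorbidity network as plain tables
#'
#' Writes the edge list (`code_i, code_j, c_ij, rr, ci_low, ci_high`) and
#' the node attributes (`code, count[, evc]`) as CSV.
#'
#' @param mn A `multimorbidity_network`.
#' @param edges_path,nodes_path Output CSV paths (`NULL` to skip one).
#' @param graphml_path Optional GraphML output path (requires the igraph
#'   package).
#' @return `mn`, invisibly.
#' @export
write_mn <- function(mn, edges_path = NULL, nodes_path = NULL, graphml_path = NULL) {
  if (!is.null(edges_path)) readr::write_csv(mn$edges, edges_path, progress = FALSE)
  if (!is.null(nodes_path)) readr::write_csv(mn$nodes, nodes_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      abort("GraphML export requires the igraph package")
    }
    g <- igraph::graph_from_data_frame(mn$edges, directed = FALSE,
      vertices = mn$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(mn)
}
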