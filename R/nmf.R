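# De novo signature extraction: bootstrapped NMF with multiplicative
# updates minimizing generalized Kullback-Leibler divergence, consensus
# clustering of bootstrap solutions, and silhouette-based rank selection.

KL_EPS <- 1e-12

kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / pmax(WH[pos], KL_EPS))) - sum(V) + sum(WH)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative channels-by-samples matrix `V` into `W %*% H`
#' with `k` components, using the multiplicative update rules that
#' monotonically decrease the generalized Kullback-Leibler divergence
#' (the conventional objective for mutational-signature extraction).
#' A Frobenius (least-squares) objective is available behind `objective`.
#'
#' @param V Non-negative numeric matrix (channels x samples).
#' @param k Number of components.
#' @param max_iter Maximum update iterations.
#' @param tol Relative objective change below which iteration stops.
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @param track_objective If `TRUE`, the per-iteration objective values are
#'   returned (used to assert monotonicity on small instances).
#' @return List with `W` (channels x k), `H` (k x samples), `objective`
#'   (final value), `iterations`, `converged`, and optionally `trace`.
#' @export
nmf_factorize <- function(V, k, max_iter = 500, tol = 1e-6,
                          objective = c("kl", "frobenius"),
                          track_objective = FALSE) {
  objective <- match.arg(objective)
  V <- as.matrix(V)
  if (any(V < 0)) rlang::abort("V must be non-negative")
  n <- ncol(V)
  m <- nrow(V)
  scale0 <- sqrt(mean(V) / k)
  W <- matrix(runif(m * k, 0.5, 1.5) * scale0, m, k)
  H <- matrix(runif(k * n, 0.5, 1.5) * scale0, k, n)
  obj_fun <- if (objective == "kl") {
    function(WH) kl_divergence(V, WH)
  } else {
    function(WH) sum((V - WH)^2) / 2
  }
  WH <- W %*% H
  last <- obj_fun(WH)
  trace <- if (track_objective) numeric(max_iter) else NULL
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    if (objective == "kl") {
      R <- V / pmax(WH, KL_EPS)
      H <- H * (crossprod(W, R) / pmax(colSums(W), KL_EPS))
      WH <- W %*% H
      R <- V / pmax(WH, KL_EPS)
      W <- W * (tcrossprod(R, H) / rep(pmax(rowSums(H), KL_EPS),
                                       each = m))
    } else {
      H <- H * (crossprod(W, V) / pmax(crossprod(W, WH), KL_EPS))
      WH <- W %*% H
      W <- W * (tcrossprod(V, H) / pmax(tcrossprod(WH, H), KL_EPS))
    }
    WH <- W %*% H
    cur <- obj_fun(WH)
    if (track_objective) trace[it] <- cur
    if (is.finite(last) && abs(last - cur) <= tol * max(abs(last), 1)) {
      converged <- TRUE
      last <- cur
      break
    }
    last <- cur
  }
  out <- list(W = W, H = H, objective = last, iterations = it,
              converged = converged)
  if (track_objective) out$trace <- trace[seq_len(it)]
  out
}

# Greedy one-to-one matching of k vectors to k centroids by cosine.
greedy_match <- function(vectors, centroids) {
  k <- ncol(centroids)
  cs <- matrix(0, ncol(vectors), k)
  for (i in seq_len(ncol(vectors))) {
    for (j in seq_len(k)) {
      cs[i, j] <- cosine_similarity(vectors[, i], centroids[, j])
    }
  }
  assign <- integer(ncol(vectors))
  used_i <- logical(ncol(vectors))
  used_j <- logical(k)
  for (step in seq_len(ncol(vectors))) {
    best <- which(cs == max(cs[!used_i, !used_j, drop = FALSE]), arr.ind = TRUE)
    best <- best[!used_i[best[, 1]] & !used_j[best[, 2]], , drop = FALSE][1, ]
    assign[best[1]] <- best[2]
    used_i[best[1]] <- TRUE
    used_j[best[2]] <- TRUE
    cs[best[1], ] <- -Inf
    cs[, best[2]] <- -Inf
  }
  assign
}

cosine_dist_matrix <- function(M) {
  nrm <- sqrt(colSums(M^2))
  d <- 1 - crossprod(M) / outer(nrm, nrm)
  d[d < 0] <- 0
  d
}

silhouette_scores <- function(M, cluster) {
  d <- cosine_dist_matrix(M)
  n <- ncol(M)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cluster == cluster[i])
    own <- setdiff(own, i)
    a <- if (length(own) == 0) 0 else mean(d[i, own])
    b <- Inf
    for (cl in setdiff(unique(cluster), cluster[i])) {
      b <- min(b, mean(d[i, cluster == cl]))
    }
    if (!is.finite(b)) {
      s[i] <- 0
    } else {
      s[i] <- (b - a) / max(a, b, KL_EPS)
    }
  }
  s
}

#' Extract mutational signatures by bootstrapped NMF
#'
#' The de novo extraction procedure: samples with a mutation total at or
#' below `min_mutations` are excluded; each bootstrap resamples every
#' remaining sample's catalog multinomially at its own total and factorizes
#' it by KL-divergence NMF; the per-bootstrap signature solutions are
#' clustered across bootstraps by greedy cosine matching to running
#' centroids, and the consensus signatures are the cluster centroids.
#' The factorization rank `k` is chosen among the ranks whose solution
#' clusters are stable — mean silhouette (cosine distance) within
#' `stability_margin` of the best rank's — as the one with the lowest
#' reconstruction error. Exposures of the original catalogs on the
#' consensus signatures are refit by non-negative least squares.
#'
#' @param catalog Wide catalog tibble from [build_catalog()] or a 96 x n
#'   matrix.
#' @param k_range Integer vector of candidate ranks.
#' @param n_bootstrap Bootstrap replicates per rank.
#' @param min_mutations Samples with totals at or below this are excluded
#'   (strict: a total of exactly `min_mutations` is excluded).
#' @param seed Master seed; per-bootstrap seeds are derived from it.
#' @param stability_margin Ranks whose mean silhouette is at least this
#'   fraction of the best rank's are considered stable; the stable rank
#'   with the lowest reconstruction error is selected.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @param objective NMF objective, `"kl"` or `"frobenius"`.
#' @return An object of class `ch_signatures`: consensus `signatures`
#'   (96 x k probability matrix), `exposures` (tibble from
#'   [fit_exposures()]), selected `k`, per-signature `stability`
#'   (mean silhouette), `reconstruction_error`, a per-rank `k_stats`
#'   tibble, and bookkeeping fields.
#' @export
extract_signatures <- function(catalog, k_range = 2:4, n_bootstrap = 100,
                               min_mutations = 100, seed = 1,
                               max_iter = 400, tol = 1e-6,
                               stability_margin = 0.9,
                               objective = c("kl", "frobenius")) {
  objective <- match.arg(objective)
  V <- catalog_matrix(catalog)
  totals <- colSums(V)
  keep <- totals > min_mutations
  excluded <- colnames(V)[!keep]
  V <- V[, keep, drop = FALSE]
  if (ncol(V) < 2 * max(k_range)) {
    rlang::abort(sprintf(
      "only %d samples exceed %d mutations; need at least %d for k up to %d",
      ncol(V), min_mutations, 2 * max(k_range), max(k_range)))
  }
  totals <- colSums(V)

  per_k <- vector("list", length(k_range))
  any_nonconverged <- FALSE
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    sols <- matrix(0, 96, k * n_bootstrap)
    cluster <- integer(k * n_bootstrap)
    centroids <- NULL
    members <- NULL
    for (b in seq_len(n_bootstrap)) {
      set.seed((seed + 100003L * k + b) %% .Machine$integer.max)
      Vb <- V
      for (j in seq_len(ncol(V))) {
        p <- V[, j] / totals[j]
        Vb[, j] <- rmultinom(1, totals[j], p)
      }
      fit <- nmf_factorize(Vb, k, max_iter = max_iter, tol = tol,
                           objective = objective)
      if (!fit$converged) any_nonconverged <- TRUE
      Wb <- fit$W
      Wb <- sweep(Wb, 2, pmax(colSums(Wb), KL_EPS), "/")
      idx <- (b - 1) * k + seq_len(k)
      if (is.null(centroids)) {
        centroids <- Wb
        members <- rep(1, k)
        cluster[idx] <- seq_len(k)
      } else {
        assign <- greedy_match(Wb, centroids)
        cluster[idx] <- assign
        for (i in seq_len(k)) {
          cl <- assign[i]
          centroids[, cl] <- (centroids[, cl] * members[cl] + Wb[, i]) /
            (members[cl] + 1)
          members[cl] <- members[cl] + 1
        }
      }
      sols[, idx] <- Wb
    }
    sil <- silhouette_scores(sols, cluster)
    sig <- sweep(centroids, 2, colSums(centroids), "/")
    expo <- matrix(vapply(seq_len(ncol(V)), function(j) {
      pracma::lsqnonneg(sig, V[, j])$x
    }, numeric(k)), nrow = k)
    err <- kl_divergence(V, sig %*% expo)
    per_k[[ki]] <- list(
      k = k, signatures = sig,
      stability = vapply(seq_len(k), function(cl) mean(sil[cluster == cl]),
                         numeric(1)),
      mean_silhouette = mean(sil), reconstruction_error = err
    )
  }

  k_stats <- tibble::tibble(
    k = vapply(per_k, `[[`, numeric(1), "k"),
    mean_silhouette = vapply(per_k, `[[`, numeric(1), "mean_silhouette"),
    reconstruction_error = vapply(per_k, `[[`, numeric(1),
                                  "reconstruction_error")
  )
  # rank selection: restrict to ranks whose solution clusters are stable
  # (mean silhouette within `stability_margin` of the best rank's), then
  # take the lowest reconstruction error among them; plain silhouette
  # maximization systematically under-fits because merging two true
  # signatures still yields tight clusters
  stable <- k_stats$mean_silhouette >=
    stability_margin * max(k_stats$mean_silhouette)
  cand <- which(stable)
  ord <- cand[order(k_stats$reconstruction_error[cand],
                    -k_stats$mean_silhouette[cand])]
  best <- per_k[[ord[1]]]
  colnames(best$signatures) <- paste0("S", seq_len(best$k))
  exposures <- fit_exposures(V, best$signatures)

  structure(list(
    signatures = best$signatures,
    exposures = exposures,
    k = best$k,
    stability = best$stability,
    reconstruction_error = best$reconstruction_error,
    k_stats = k_stats,
    excluded_samples = excluded,
    converged = !any_nonconverged,
    n_bootstrap = n_bootstrap,
    objective = objective
  ), class = "ch_signatures")
}

#' Refit per-sample signature exposures by non-negative least squares
#'
#' Attributes each sample's 96-channel catalog to a fixed set of signature
#' profiles by NNLS on counts, so exposures are in mutation counts. When
#' signatures are nearly collinear (pairwise cosine > 0.999) the fit is
#' still returned and a warning is raised.
#'
#' @param catalog Wide catalog tibble or 96 x n matrix.
#' @param signatures Signature profiles: 96 x k matrix or wide tibble with
#'   a `channel` column.
#' @return Tibble with `sample_id`, one exposure column per signature, and
#'   `residual` (Euclidean residual norm of the fit).
#' @export
fit_exposures <- function(catalog, signatures) {
  V <- catalog_matrix(catalog)
  S <- as_signature_matrix(signatures)
  if (ncol(S) > 1) {
    cs <- crossprod(S) / outer(sqrt(colSums(S^2)), sqrt(colSums(S^2)))
    if (any(cs[upper.tri(cs)] > 0.999)) {
      rlang::warn("near-collinear signatures: exposure split is unstable")
    }
  }
  fits <- apply(V, 2, function(v) {
    f <- pracma::lsqnonneg(S, v)
    c(f$x, sqrt(max(f$resid.norm, 0)))
  })
  fits <- matrix(fits, nrow = ncol(S) + 1)
  out <- tibble::as_tibble(as.data.frame(t(fits[seq_len(ncol(S)), ,
                                                drop = FALSE])))
  names(out) <- colnames(S) %||% paste0("S", seq_len(ncol(S)))
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(V)), out,
                   tibble::tibble(residual = fits[ncol(S) + 1, ]))
}

#' Match extracted signatures to a reference catalog by cosine similarity
#'
#' Pairs each extracted signature with its maximum-cosine reference
#' profile. References whose name appears in `artifact_names` and match
#' above `artifact_threshold` are flagged, mirroring the vetting of
#' extraction solutions against known sequencing-artifact signatures.
#'
#' @param extracted,reference Signature sets (96 x k matrices or wide
#'   tibbles with a `channel` column).
#' @param artifact_names Character vector of reference names considered
#'   artifacts.
#' @param artifact_threshold Cosine above which an artifact match is
#'   flagged.
#' @return Tibble with `extracted`, `reference`, `cosine`, `is_artifact`.
#' @export
match_to_reference <- function(extracted, reference, artifact_names = character(),
                               artifact_threshold = 0.8) {
  E <- as_signature_matrix(extracted)
  R <- as_signature_matrix(reference)
  if (ncol(R) == 0) rlang::abort("empty reference set")
  en <- colnames(E) %||% paste0("S", seq_len(ncol(E)))
  rn <- colnames(R) %||% paste0("R", seq_len(ncol(R)))
  purrr::map_dfr(seq_len(ncol(E)), function(i) {
    cs <- vapply(seq_len(ncol(R)), function(j) {
      cosine_similarity(E[, i], R[, j])
    }, numeric(1))
    j <- which.max(cs)
    tibble::tibble(
      extracted = en[i], reference = rn[j], cosine = cs[j],
      is_artifact = rn[j] %in% artifact_names & cs[j] >= artifact_threshold
    )
  })
}

#' @export
print.ch_signatures <- function(x, ...) {
  cat(sprintf(
    "<ch_signatures> k = %d (silhouette-selected from {%s})\n",
    x$k, paste(x$k_stats$k, collapse = ", ")))
  cat(sprintf("  stability: %s\n",
              paste(sprintf("%.3f", x$stability), collapse = ", ")))
  cat(sprintf("  reconstruction error (KL): %.1f\n", x$reconstruction_error))
  cat(sprintf("  samples fit: %d (excluded below mutation floor: %d)\n",
              nrow(x$exposures), length(x$excluded_samples)))
  invisible(x)
}

#' Tidy the consensus signatures of an extraction
#'
#' @param x A `ch_signatures` object.
#' @param ... Unused.
#' @return Long tibble with `signature`, `channel`, `prob`.
#' @exportS3Method generics::tidy
#' @export
tidy.ch_signatures <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$signatures)) |>
    dplyr::mutate(channel = rownames(x$signatures)) |>
    tidyr::pivot_longer(-"channel", names_to = "signature",
                        values_to = "prob") |>
    dplyr::arrange(.data$signature)
}

#' One-row summary of a signature extraction
#'
#' @param x A `ch_signatures` object.
#' @param ... Unused.
#' @return One-row tibble with the selected rank, mean stability,
#'   reconstruction error and sample counts.
#' @exportS3Method generics::glance
#' @export
glance.ch_signatures <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    mean_stability = mean(x$stability),
    reconstruction_error = x$reconstruction_error,
    n_samples = nrow(x$exposures),
    n_excluded = length(x$excluded_samples),
    converged = x$converged
  )
}
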