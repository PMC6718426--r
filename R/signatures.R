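#' Trinucleotide mutation channels
#'
#' The 96 single-base-substitution channels in pyrimidine-strand
#' convention, ordered by substitution class (C>A, C>G, C>T, T>A, T>C,
#' T>G), then 5' base, then 3' base (A, C, G, T each).
#'
#' @return Character vector of 96 channel names like `"A[C>A]A"`.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (p5 in bases) for (p3 in bases)
    out <- c(out, paste0(p5, "[", s, "]", p3))
  out
}

.revcomp <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
}

#' Build a 96-channel mutation catalog
#'
#' Tabulates single-nucleotide variants into trinucleotide-context
#' channels. Variants with a purine reference base are folded onto the
#' pyrimidine strand by reverse complementing the context and
#' complementing the alternative allele, so each SNV lands in exactly
#' one channel.
#'
#' @param v variant table (only rows with single-base ref and alt are
#'   used; others are ignored).
#' @param reference a named `DNAStringSet` (names = chromosomes) or the
#'   path of a FASTA file.
#' @return Named integer vector of 96 counts in [sbs_channels()] order.
#' @export
build_catalog <- function(v, reference) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  stopifnot(methods::is(reference, "DNAStringSet"))
  names(reference) <- sub("\\s.*$", "", names(reference))
  channels <- sbs_channels()
  counts <- stats::setNames(integer(96), channels)
  if (is.null(v) || !nrow(v)) return(counts)
  snv <- v[nchar(v$ref) == 1 & nchar(v$alt) == 1 &
             v$ref %in% c("A", "C", "G", "T") &
             v$alt %in% c("A", "C", "G", "T"), , drop = FALSE]
  if (!nrow(snv)) return(counts)
  for (i in seq_len(nrow(snv))) {
    chrom <- snv$chrom[i]; pos <- snv$pos[i]
    if (!chrom %in% names(reference))
      stop("chromosome not in reference: ", chrom)
    seq <- reference[[chrom]]
    if (pos < 2 || pos > length(seq) - 1)
      stop("position too close to contig edge: ", chrom, ":", pos)
    ctx <- as.character(Biostrings::subseq(seq, pos - 1, pos + 1))
    ref_base <- substr(ctx, 2, 2)
    if (ref_base != snv$ref[i])
      stop("reference mismatch at ", chrom, ":", pos,
           " (reference ", ref_base, ", variant ref ", snv$ref[i], ")")
    alt <- snv$alt[i]
    if (ref_base %in% c("A", "G")) {       # fold to pyrimidine strand
      ctx <- .revcomp(ctx)
      alt <- .revcomp(alt)
      ref_base <- substr(ctx, 2, 2)
    }
    ch <- paste0(substr(ctx, 1, 1), "[", ref_base, ">", alt, "]",
                 substr(ctx, 3, 3))
    counts[ch] <- counts[ch] + 1L
  }
  counts
}

#' Construct / validate a signature set
#'
#' @param mat 96 x K non-negative matrix whose columns each sum to 1
#'   (within 1e-8); rows in [sbs_channels()] order.
#' @param names optional signature names (otherwise column names).
#' @return The validated matrix with class `signature_set`.
#' @export
signature_set <- function(mat, names = colnames(mat)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 96) stop("signature matrix must have 96 rows")
  if (any(mat < 0)) stop("signature matrix must be non-negative")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-8))
    stop("signature columns must sum to 1 (within 1e-8)")
  if (is.null(names)) names <- paste0("S", seq_len(ncol(mat)))
  colnames(mat) <- names
  rownames(mat) <- sbs_channels()
  class(mat) <- c("signature_set", class(mat))
  mat
}

#' Synthetic reference signature set
#'
#' A code-constructed stand-in for a published reference signature
#' catalog, with the qualitative character of the processes discussed in
#' mucinous ovarian tumors: `Sig1` (age-related, C>T at NpCpG), `Sig2`
#' (APOBEC, C>T at TpCpN), `Sig13` (APOBEC, C>G at TpCpN), `Sig8`
#' (broad C>A) and `Flat` (uniform background). It is synthetic — the
#' channel weights are invented, not fitted to data — and is intended
#' for refitting demonstrations and tests.
#'
#' @return A [signature_set()] with 5 columns.
#' @export
synthetic_signature_set <- function() {
  channels <- sbs_channels()
  base <- function() rep(1 / 96, 96)
  spike <- function(pattern, mass) {
    idx <- grep(pattern, channels)
    w <- rep((1 - mass) / 96, 96)
    w[idx] <- w[idx] + mass / length(idx)
    w
  }
  mat <- cbind(
    Sig1  = spike("\\[C>T\\]G$", 0.85),
    Sig2  = spike("^T\\[C>T\\]", 0.85),
    Sig13 = spike("^T\\[C>G\\]", 0.85),
    Sig8  = spike("\\[C>A\\]", 0.75),
    Flat  = base()
  )
  signature_set(mat)
}

#' Refit known signatures to a catalog (forward selection)
#'
#' Greedy forward selection: at each step the signature whose admission
#' most reduces the squared reconstruction error of the normalized
#' catalog (weights fitted by non-negative least squares) is added;
#' selection stops when the relative improvement falls below `rel_tol`.
#' Fitted weights below the sparsity cutoff are zeroed and the surviving
#' set is refitted. The procedure is deterministic.
#'
#' @param catalog named 96-vector of counts (total > 0).
#' @param signatures a [signature_set()].
#' @param sparsity weights below this value are set to exactly 0
#'   (default 0.06).
#' @param rel_tol stopping threshold on relative error improvement.
#' @return List with `weights` (named, >= 0, sum <= 1), `residual`
#'   (squared reconstruction error) and `major` (name of the largest
#'   component).
#' @export
refit_signatures <- function(catalog, signatures, sparsity = 0.06,
                             rel_tol = 1e-3) {
  P <- unclass(signatures)
  stopifnot(nrow(P) == 96, length(catalog) == 96)
  total <- sum(catalog)
  if (total <= 0) stop("catalog has zero mutations; nothing to refit")
  m <- as.numeric(catalog) / total
  K <- ncol(P)
  nnls_fit <- function(cols) {
    fit <- pracma::lsqnonneg(P[, cols, drop = FALSE], m)
    list(w = fit$x, sse = sum((m - P[, cols, drop = FALSE] %*% fit$x)^2))
  }
  selected <- integer(0)
  sse <- sum(m^2)
  repeat {
    cand <- setdiff(seq_len(K), selected)
    if (!length(cand)) break
    fits <- lapply(cand, function(j) nnls_fit(c(selected, j)))
    best <- which.min(vapply(fits, `[[`, 0, "sse"))
    if ((sse - fits[[best]]$sse) / sse < rel_tol) break
    selected <- c(selected, cand[best])
    sse <- fits[[best]]$sse
  }
  w <- stats::setNames(numeric(K), colnames(P))
  if (length(selected)) {
    fit <- nnls_fit(selected)
    wk <- fit$w
    wk[wk < sparsity] <- 0
    keep <- selected[wk > 0]
    if (length(keep)) {
      fit <- nnls_fit(keep)
      wk <- fit$w
      wk[wk < sparsity] <- 0
      if (sum(wk) > 1) wk <- wk / sum(wk)
      w[keep] <- wk
    }
  }
  resid <- sum((m - P %*% w)^2)
  list(weights = w, residual = resid,
       major = if (any(w > 0)) names(w)[which.max(w)] else NA_character_)
}

#' De novo signature discovery by NMF
#'
#' Factorizes a 96 x n catalog matrix as W H with multiplicative
#' updates minimizing Frobenius reconstruction error (which is
#' non-increasing across iterations). The best of `restarts` seeded
#' random initializations is kept; signature columns are normalized to
#' sum to 1 with exposures rescaled accordingly.
#'
#' @param catalogs 96 x n matrix of counts (cases in columns), or a list
#'   of catalog vectors.
#' @param k number of signatures (default 3).
#' @param restarts random initializations (default 50).
#' @param seed RNG seed; the factorization is reproducible given it.
#' @param max_iter,tol iteration cap and relative-error convergence
#'   tolerance per run.
#' @return List with `signatures` (a [signature_set()]), `exposures`
#'   (k x n), `error` (Frobenius error of the best run) and
#'   `error_trace` (per-iteration errors of the best run).
#' @export
discover_signatures_nmf <- function(catalogs, k = 3, restarts = 50,
                                    seed = 1, max_iter = 2000, tol = 1e-10) {
  V <- if (is.list(catalogs) && !is.matrix(catalogs))
    do.call(cbind, catalogs) else as.matrix(catalogs)
  stopifnot(nrow(V) == 96)
  if (any(V < 0)) stop("catalog counts must be non-negative")
  if (any(colSums(V) <= 0)) stop("every catalog must have positive total")
  n <- ncol(V)
  if (k > n) stop("k exceeds the number of catalogs")
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    W <- matrix(stats::runif(96 * k, 0.1, 1), 96, k)
    H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
    err_prev <- Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err <- sum((V - W %*% H)^2)
      trace <- c(trace, err)
      if (is.finite(err_prev) && (err_prev - err) / max(err_prev, eps) < tol)
        break
      err_prev <- err
    }
    if (is.null(best) || err < best$error)
      best <- list(W = W, H = H, error = err, trace = trace)
  }
  scale <- colSums(best$W)
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  rownames(H) <- paste0("S", seq_len(k))
  list(signatures = signature_set(W, paste0("S", seq_len(k))),
       exposures = H, error = best$error, error_trace = best$trace)
}

#' Cosine similarity between signature columns, with best matching
#'
#' Matches each estimated signature to a distinct truth signature by the
#' permutation maximizing the mean cosine similarity.
#'
#' @param est,truth matrices with signatures in columns (equal k).
#' @return List with `similarity` (per matched pair) and `matching`
#'   (index of the truth column matched to each estimated column).
#' @export
match_signatures <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  k <- ncol(est)
  stopifnot(ncol(truth) == k)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- outer(seq_len(k), seq_len(k),
               Vectorize(function(i, j) cosine(est[, i], truth[, j])))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- NULL; best_mean <- -Inf
  for (p in perms(seq_len(k))) {
    m <- mean(sim[cbind(seq_len(k), p)])
    if (m > best_mean) { best_mean <- m; best <- p }
  }
  list(similarity = sim[cbind(seq_len(k), best)], matching = best)
}
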