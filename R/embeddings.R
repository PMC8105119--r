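# Paired input/output word-vector store in word2vec text format, plus the
# cosine and sentence-context primitives the metaphor identifier uses.
# Context matching uses input vectors; sense-difference scoring uses
# output vectors, so both parameter matrices of a CBOW/Skip-Gram model
# must be exported.

#' Load an embedding store from two word2vec text files
#'
#' Each file starts with a header line `count dim` followed by one line
#' per word: the word then `dim` floats. The two files hold the input
#' (projection) and output (context/softmax) matrices of the same model;
#' the store keeps the intersection of their vocabularies and warns about
#' words present in only one file.
#'
#' @param input_path path to the input-vector file.
#' @param output_path path to the output-vector file.
#' @param flavor metadata tag, `"skipgram"` (default) or `"cbow"`.
#' @return list of class `msm_embeddings` with `vocab`, `dim`, `input`
#'   and `output` (numeric matrices, one row per word) and `flavor`.
#' @export
load_embeddings <- function(input_path, output_path,
                            flavor = c("skipgram", "cbow")) {
  flavor <- match.arg(flavor)
  inp <- read_w2v(input_path)
  out <- read_w2v(output_path)
  if (ncol(inp) != ncol(out))
    stop("dimension mismatch: input dim ", ncol(inp), " vs output dim ",
         ncol(out), call. = FALSE)
  common <- intersect(rownames(inp), rownames(out))
  dropped <- setdiff(union(rownames(inp), rownames(out)), common)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " word(s) absent from one matrix: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (length(common) == 0L)
    stop("input and output vocabularies do not overlap", call. = FALSE)
  embedding_store(inp[common, , drop = FALSE],
                  out[common, , drop = FALSE], flavor)
}

#' Construct an embedding store from in-memory matrices
#'
#' @param input,output numeric matrices with the same words as rownames
#'   and the same number of columns.
#' @param flavor `"skipgram"` or `"cbow"` (metadata only).
#' @return an `msm_embeddings` store.
#' @export
embedding_store <- function(input, output, flavor = "skipgram") {
  stopifnot(is.matrix(input), is.matrix(output),
            identical(rownames(input), rownames(output)),
            ncol(input) == ncol(output),
            all(is.finite(input)), all(is.finite(output)))
  structure(list(vocab = rownames(input), dim = ncol(input),
                 input = input, output = output, flavor = flavor),
            class = "msm_embeddings")
}

read_w2v <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop(path, ": malformed word2vec header '", lines[1], "'", call. = FALSE)
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (length(lines) - 1L != n)
    stop(path, ": header promises ", n, " rows, found ", length(lines) - 1L,
         call. = FALSE)
  words <- character(n)
  mat <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(f) != d + 1L)
      stop(path, ": line ", i + 1L, " has ", length(f) - 1L,
           " values, expected ", d, call. = FALSE)
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v))
      stop(path, ": non-numeric field on line ", i + 1L, call. = FALSE)
    words[i] <- f[1]
    mat[i, ] <- v
  }
  if (!all(is.finite(mat)))
    stop(path, ": non-finite vector component", call. = FALSE)
  rownames(mat) <- words
  mat
}

#' Write an embedding matrix in word2vec text format
#'
#' @param mat numeric matrix with words as rownames.
#' @param path destination file.
#' @param digits significant digits for vector components (default 8).
#' @export
write_w2v <- function(mat, path, digits = 8) {
  hdr <- paste(nrow(mat), ncol(mat))
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(rownames(mat)[i],
          paste(formatC(mat[i, ], digits = digits, format = "g"),
                collapse = " "))
  }, character(1))
  writeLines(c(hdr, rows), path)
}

#' @export
print.msm_embeddings <- function(x, ...) {
  cat("<msm_embeddings> ", length(x$vocab), " words, dim ", x$dim,
      ", flavor ", x$flavor, "\n", sep = "")
  invisible(x)
}

#' Cosine similarity
#'
#' @param u,v numeric vectors of equal length; neither may be the zero
#'   vector (that is an error, never silently 0).
#' @return scalar in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    stop("cosine undefined for a zero vector", call. = FALSE)
  s <- sum(u * v) / (nu * nv)
  min(1, max(-1, s))
}

# look a token up in the store: lowercase surface first, then lemma
store_index <- function(store, surface, lemma) {
  i <- match(tolower(surface), store$vocab)
  j <- match(tolower(lemma), store$vocab)
  ifelse(is.na(i), j, i)
}

#' Average input vector of a detected word's sentence context
#'
#' The context is every in-vocabulary token of the sentence except the
#' detected one — the whole sentence by default, or a symmetric window of
#' `window` tokens on each side when `window > 0`. Out-of-vocabulary
#' context tokens are skipped. When no in-vocabulary context token
#' remains the function returns `NULL` (the no-context signal; the caller
#' skips the word and labels it literal).
#'
#' @param sentence a sentence element of an `msm_document`.
#' @param detected_index 0-based index of the detected token.
#' @param store an `msm_embeddings`.
#' @param window 0 for the whole sentence (default) or a positive
#'   symmetric window size.
#' @return numeric vector of length `store$dim`, or `NULL`.
#' @export
context_vector <- function(sentence, detected_index, store, window = 0) {
  tok <- sentence$tokens
  pos_in_df <- match(detected_index, tok$index)
  stopifnot(!is.na(pos_in_df))
  keep <- seq_len(nrow(tok)) != pos_in_df
  if (window > 0)
    keep <- keep & abs(tok$index - detected_index) <= window
  idx <- store_index(store, tok$surface[keep], tok$lemma[keep])
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(NULL)
  colMeans(store$input[idx, , drop = FALSE])
}
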