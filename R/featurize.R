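#' Featurizer configuration
#'
#' N-gram extraction settings for the question classifier. The default —
#' character units, N from 1 to 5 — suits languages without whitespace word
#' boundaries (the setting the system was designed around for Japanese);
#' `unit = "word"` with whitespace tokenisation suits Latin-script text.
#'
#' @param unit `"character"` or `"word"`.
#' @param n_min,n_max Smallest and largest N; `1 <= n_min <= n_max`.
#' @param lowercase Lowercase during normalisation.
#' @param vocabulary Optional ordered character vector of N-grams. When set,
#'   [vectorize()] uses exactly these columns and drops out-of-vocabulary
#'   N-grams.
#' @param min_document_frequency Drop N-grams occurring in fewer than this
#'   many corpus documents when building a vocabulary (default 1 = keep all).
#' @return An object of class `featurizer_config`.
#' @export
featurizer_config <- function(unit = c("character", "word"),
                              n_min = 1L, n_max = 5L,
                              lowercase = TRUE,
                              vocabulary = NULL,
                              min_document_frequency = 1L) {
  unit <- match.arg(unit)
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 1L || n_max < n_min)
    stop("need 1 <= n_min <= n_max", call. = FALSE)
  if (!is.null(vocabulary)) {
    vocabulary <- as.character(vocabulary)
    if (anyDuplicated(vocabulary))
      stop("vocabulary entries must be unique", call. = FALSE)
  }
  structure(
    list(unit = unit, n_min = n_min, n_max = n_max, lowercase = lowercase,
         vocabulary = vocabulary,
         min_document_frequency = as.integer(min_document_frequency)),
    class = "featurizer_config"
  )
}

# Unicode NFKC, optional lowercasing, punctuation folded into token
# boundaries. Character unit keeps letters/digits only; word unit splits on
# whitespace.
normalize_utterance <- function(text, cfg) {
  x <- stringi::stri_trans_nfkc(text)
  if (isTRUE(cfg$lowercase)) x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  x
}

tokenize_utterance <- function(text, cfg) {
  x <- normalize_utterance(text, cfg)
  if (!nzchar(x)) return(character(0))
  if (cfg$unit == "word") {
    strsplit(x, " ", fixed = TRUE)[[1]]
  } else {
    # character unit: whitespace is not a token
    strsplit(gsub(" ", "", x, fixed = TRUE), "")[[1]]
  }
}

#' Extract N-gram frequency features from one utterance
#'
#' Slides windows of every length in `[n_min, n_max]` over the token
#' sequence (characters or words) and counts occurrences. Windows longer
#' than the sequence contribute nothing.
#'
#' @param text A single utterance.
#' @param cfg A [featurizer_config()].
#' @return Named integer vector: N-gram string -> frequency (>= 1). Absent
#'   N-grams are implicitly zero.
#' @examples
#' extract_ngrams("Tell me what happened",
#'                featurizer_config("word", n_min = 2, n_max = 2))
#' @export
extract_ngrams <- function(text, cfg = featurizer_config()) {
  stopifnot(length(text) == 1L)
  toks <- tokenize_utterance(text, cfg)
  if (length(toks) == 0L)
    stop("empty utterance after normalization", call. = FALSE)
  sep <- if (cfg$unit == "word") " " else ""
  grams <- character(0)
  for (n in cfg$n_min:cfg$n_max) {
    L <- length(toks)
    if (L < n) next
    if (n == 1L) {
      grams <- c(grams, toks)
    } else {
      m <- vapply(seq_len(L - n + 1L),
                  function(i) paste(toks[i:(i + n - 1L)], collapse = sep),
                  character(1))
      grams <- c(grams, m)
    }
  }
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build an N-gram document-term matrix
#'
#' Featurises a corpus into a sparse matrix whose columns follow the
#' vocabulary order. With a fixed vocabulary (in `cfg` or via `vocabulary`),
#' out-of-vocabulary N-grams of new texts are dropped; otherwise the
#' vocabulary is built from `texts` (sorted, unique, filtered by
#' `min_document_frequency`).
#'
#' @param texts Character vector of utterances.
#' @param cfg A [featurizer_config()].
#' @param vocabulary Optional vocabulary overriding `cfg$vocabulary`.
#' @return List with `matrix` (a `dgCMatrix`, rows = texts, columns =
#'   vocabulary) and `vocabulary` (ordered character vector).
#' @export
vectorize <- function(texts, cfg = featurizer_config(), vocabulary = NULL) {
  if (length(texts) == 0L) stop("empty corpus", call. = FALSE)
  feats <- lapply(texts, extract_ngrams, cfg = cfg)
  vocab <- vocabulary %||% cfg$vocabulary
  if (is.null(vocab)) {
    all_names <- unlist(lapply(feats, names), use.names = FALSE)
    if (cfg$min_document_frequency > 1L) {
      df <- table(unlist(lapply(feats, function(f) unique(names(f)))))
      keep <- names(df)[df >= cfg$min_document_frequency]
      vocab <- sort(unique(all_names[all_names %in% keep]))
    } else {
      vocab <- sort(unique(all_names))
    }
  }
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (i in seq_along(feats)) {
    j <- match(names(feats[[i]]), vocab)
    ok <- !is.na(j)
    ii <- c(ii, rep.int(i, sum(ok)))
    jj <- c(jj, j[ok])
    xx <- c(xx, unname(feats[[i]])[ok])
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                            dims = c(length(texts), length(vocab)),
                            dimnames = list(NULL, vocab))
  list(matrix = m, vocabulary = vocab)
}

#' Jaccard similarity of two feature sets
#'
#' Presence/absence similarity between the N-gram key sets of two feature
#' vectors: `|intersection| / |union|`. Frequencies are ignored — the
#' coefficient disregards N-grams absent from both utterances, which matches
#' sparse question data where almost every vocabulary N-gram is absent from
#' any given question. Used for repetition detection between consecutive
#' questions. Two empty sets return 0 (no evidence of similarity).
#'
#' @param a,b Named numeric vectors as returned by [extract_ngrams()].
#' @return Similarity in `[0, 1]`.
#' @examples
#' a <- c(ab = 1, bc = 2); b <- c(bc = 1, cd = 1)
#' jaccard(a, b)  # 1/3
#' @export
jaccard <- function(a, b) {
  ka <- names(a)[a > 0]; kb <- names(b)[b > 0]
  u <- length(union(ka, kb))
  if (u == 0L) return(0)
  length(intersect(ka, kb)) / u
}

#' Write / read a vocabulary as newline-delimited text
#'
#' @param vocabulary Ordered character vector.
#' @param path File path.
#' @return `path` (write) or the vocabulary (read).
#' @export
write_vocabulary <- function(vocabulary, path) {
  writeLines(vocabulary, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  readLines(path, encoding = "UTF-8")
}
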