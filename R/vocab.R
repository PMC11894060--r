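# SMILES tokenization against the fixed chemical-language vocabulary.
#
# The full vocabulary has 108 tokens; pruning the 14 infrequent bracket
# tokens leaves the 94-token vocabulary used for model input. Tokens are
# single characters except 'Br', 'Cl', the ring-closure escapes
# '%10'/'%11'/'%12' and bracket atoms, which are atomic entries.
# Tokenization is greedy longest-match with a bracket fast path: '['
# always opens one token closed at the next ']'.
#
# Specials: '<' (part of the printed vocabulary) is the begin-of-sequence
# token; a pad token '>' is appended to the vocabulary for batching and
# doubles as end-of-sequence.

BEGIN_TOKEN <- "<"
PAD_TOKEN <- ">"

#' The fixed SMILES vocabulary
#'
#' Loads the vocabulary shipped with the package: 108 tokens in full
#' form, or 94 after removing the infrequent tokens.
#'
#' @param pruned If `TRUE` (default) return the pruned 94-token
#'   vocabulary; otherwise the full 108-token one.
#' @return An object of class `smiles_vocab`: a list with `tokens` (the
#'   file entries, order fixed), `begin`, `pad`, and `ids` (named
#'   integer map including the pad token appended after the file
#'   entries).
#' @examples
#' length(smiles_vocabulary()$tokens)
#' @export
smiles_vocabulary <- function(pruned = TRUE) {
  path <- system.file(
    "extdata", if (pruned) "vocab_pruned.txt" else "vocab_full.txt",
    package = "phoregen", mustWork = TRUE)
  tokens <- readLines(path)
  if (anyDuplicated(tokens)) stop("duplicate tokens in vocabulary file")
  all_tokens <- c(tokens, PAD_TOKEN)
  structure(
    list(tokens = tokens, begin = BEGIN_TOKEN, pad = PAD_TOKEN,
         ids = stats::setNames(seq_along(all_tokens), all_tokens)),
    class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("<smiles_vocab> ", length(x$tokens), " tokens (+pad)\n", sep = "")
  invisible(x)
}

vocab_hash <- function(vocab) {
  # order-sensitive content hash; checkpoints refuse to load on mismatch
  sum(vapply(seq_along(vocab$tokens),
             function(i) i * sum(utf8ToInt(vocab$tokens[i])), numeric(1)))
}

#' Tokenize a SMILES string
#'
#' Greedy longest-match segmentation against the vocabulary; the
#' concatenation of the returned tokens reproduces the input exactly.
#' Strings containing substrings outside the vocabulary are rejected with
#' the offending position.
#'
#' @param smiles A single SMILES string.
#' @param vocab A [smiles_vocabulary()].
#' @return Character vector of tokens.
#' @examples
#' tokenize_smiles("CCBr")
#' @export
tokenize_smiles <- function(smiles, vocab = smiles_vocabulary()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  tokset <- vocab$ids
  maxlen <- max(nchar(names(tokset)))
  out <- character(0)
  i <- 1L
  n <- nchar(smiles)
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (j < 0) stop_oov(smiles, i, substr(smiles, i, n))
      tok <- substr(smiles, i, i + j - 1L)
      if (is.na(tokset[tok])) stop_oov(smiles, i, tok)
      out <- c(out, tok)
      i <- i + j
    } else {
      hit <- NA_character_
      for (l in seq(min(maxlen, n - i + 1L), 1L)) {
        cand <- substr(smiles, i, i + l - 1L)
        if (!is.na(tokset[cand])) { hit <- cand; break }
      }
      if (is.na(hit)) stop_oov(smiles, i, ch)
      out <- c(out, hit)
      i <- i + nchar(hit)
    }
  }
  out
}

stop_oov <- function(smiles, pos, tok) {
  cnd <- structure(
    class = c("phoregen_oov", "error", "condition"),
    list(message = sprintf(
      "out-of-vocabulary token '%s' at position %d of '%s'",
      tok, pos, smiles), call = NULL, position = pos, token = tok))
  stop(cnd)
}

#' Check a corpus against the vocabulary
#'
#' @param data Data frame with a SMILES column, or character vector.
#' @param smiles_col Column holding SMILES strings.
#' @inheritParams tokenize_smiles
#' @return The input as a tibble with logical `in_vocab` and character
#'   `oov_token` (`NA` where tokenizable) columns.
#' @examples
#' vocab_check(c("CCO", "CC[Xe]"))
#' @export
vocab_check <- function(data, smiles_col = smiles,
                        vocab = smiles_vocabulary()) {
  data <- as_smiles_tibble(data)
  smi <- dplyr::pull(data, {{ smiles_col }})
  res <- lapply(smi, function(s) {
    tryCatch({ tokenize_smiles(s, vocab); list(TRUE, NA_character_) },
             phoregen_oov = function(e) list(FALSE, e$token))
  })
  data$in_vocab <- vapply(res, function(x) x[[1]], logical(1))
  data$oov_token <- vapply(res, function(x) x[[2]], character(1))
  data
}

#' Encode tokens to model ids and decode back
#'
#' `encode_tokens()` maps a token vector to integer ids, prepending the
#' begin token; `decode_ids()` inverts the mapping, dropping begin and
#' stopping at the first pad/end token, and returns the SMILES string.
#'
#' @param tokens Character vector of vocabulary tokens.
#' @param ids Integer vector of token ids.
#' @inheritParams tokenize_smiles
#' @return `encode_tokens()`: integer vector; `decode_ids()`: a SMILES
#'   string.
#' @examples
#' decode_ids(encode_tokens(tokenize_smiles("c1ccccc1")))
#' @export
encode_tokens <- function(tokens, vocab = smiles_vocabulary()) {
  ids <- vocab$ids[c(BEGIN_TOKEN, tokens)]
  if (anyNA(ids)) {
    stop("unknown token(s): ",
         paste(c(BEGIN_TOKEN, tokens)[is.na(ids)], collapse = ", "))
  }
  unname(ids)
}

#' @rdname encode_tokens
#' @export
decode_ids <- function(ids, vocab = smiles_vocabulary()) {
  tokens <- names(vocab$ids)[ids]
  tokens <- tokens[tokens != BEGIN_TOKEN]
  stop_at <- which(tokens == PAD_TOKEN)
  if (length(stop_at)) tokens <- tokens[seq_len(stop_at[1] - 1L)]
  paste(tokens, collapse = "")
}
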