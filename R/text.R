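#' Tokenize short clinical free-text
#'
#' Lower-cases and splits on whitespace and punctuation. A question mark is
#' retained attached to its preceding token ("menopause?" stays one token),
#' because trailing "?" is one of the uncertainty constructions the negation
#' filter must recognise.
#'
#' @param text character scalar (<= 255 characters in the source tables).
#' @return Character vector of tokens; empty input gives `character(0)`.
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^a-z0-9?]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1L]]
  toks <- sub("^\\?+", "", toks)          # leading "?" belongs to no token
  toks <- sub("(\\?)\\?+$", "\\1", toks)  # collapse repeated trailing "?"
  toks[nzchar(toks)]
}

#' Unigrams and adjacent bigrams of a token sequence
#'
#' @param tokens character vector as produced by [tokenize()].
#' @return Character vector: all distinct unigrams plus all distinct adjacent
#'   ordered bigrams ("a b").
#' @export
extract_ngrams <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) return(character(0))
  uni <- tokens
  if (n >= 2L) {
    bi <- paste(tokens[-n], tokens[-1L])
    unique(c(uni, bi))
  } else {
    unique(uni)
  }
}

#' Default negation / uncertainty lexicon
#'
#' Fifty templates describing negated or uncertain mentions of a target term,
#' each with a `{term}` slot (e.g. "not {term}", "{term}?",
#' "rule out {term}"). Shipped as a plain-text file so the lexicon is
#' configuration, not code.
#'
#' @param path optional path to an alternative template file (one template
#'   per line, `#` comments allowed).
#' @return Character vector of templates, class `negation_lexicon`.
#' @export
default_negation_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "negation_lexicon.txt",
                        package = "phenoforge", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("negation lexicon is empty: ", path)
  if (!all(grepl("\\{term\\}", lines, fixed = FALSE)))
    stop("every lexicon template must contain a {term} slot")
  structure(lines, class = "negation_lexicon")
}

#' Default phenotype target-term patterns
#'
#' Regular expressions identifying the tokens whose negated or uncertain
#' mentions must be suppressed: the "menopaus*" family (menopause,
#' menopausal, postmenopausal, perimenopausal, ...) and "climacteric".
#'
#' @return Character vector of regular expressions matched against tokens.
#' @export
default_target_terms <- function() {
  c("menopaus", "climacteric")
}

token_is_target <- function(tokens, target_terms) {
  bare <- sub("\\?$", "", tokens)
  hit <- rep(FALSE, length(tokens))
  for (re in target_terms) hit <- hit | grepl(re, bare)
  hit
}

## Compile a template into its token sequence; the slot token is "{term}"
## (plain mention) or "{term}?" (mention with attached question mark).
compile_template <- function(template) {
  protected <- gsub("\\{term\\}", "xtermslotx", template)
  toks <- tokenize(protected)
  toks <- sub("xtermslotx", "{term}", toks, fixed = TRUE)
  if (sum(grepl("{term}", toks, fixed = TRUE)) != 1L)
    stop("template must contain exactly one usable {term} slot: ", template)
  toks
}

#' Remove negated or uncertain target-term mentions from text
#'
#' Scans the tokenized text for any lexicon template instantiated with a
#' target term and deletes the target-term token of each match before n-gram
#' extraction. The deletion is scoped to the mention: affirmative mentions
#' and unrelated tokens in the same record survive ("not menopause; hot
#' flashes" loses only "menopause").
#'
#' @param text character scalar.
#' @param lexicon templates from [default_negation_lexicon()].
#' @param target_terms regexes from [default_target_terms()].
#' @return Filtered text, re-joined with single spaces (possibly "").
#' @export
filter_negated <- function(text, lexicon = default_negation_lexicon(),
                           target_terms = default_target_terms()) {
  toks <- filter_negated_tokens(tokenize(text), lexicon, target_terms)
  paste(toks, collapse = " ")
}

filter_negated_tokens <- function(tokens, lexicon, target_terms) {
  n <- length(tokens)
  if (n == 0L) return(tokens)
  is_target <- token_is_target(tokens, target_terms)
  if (!any(is_target)) return(tokens)
  has_q <- grepl("\\?$", tokens)
  drop <- rep(FALSE, n)
  for (tpl in lexicon) {
    tt <- compile_template(tpl)
    m <- length(tt)
    if (m > n) next
    slot <- which(tt %in% c("{term}", "{term}?"))
    slot_q <- identical(tt[slot], "{term}?")
    for (start in seq_len(n - m + 1L)) {
      idx <- start:(start + m - 1L)
      tpos <- idx[slot]
      if (!is_target[tpos]) next
      if (slot_q && !has_q[tpos]) next
      fixed_ok <- TRUE
      for (j in seq_len(m)) {
        if (j == slot) next
        if (tokens[idx[j]] != tt[j]) { fixed_ok <- FALSE; break }
      }
      if (fixed_ok) drop[tpos] <- TRUE
    }
  }
  tokens[!drop]
}

## Tokens ready for feature extraction: negation-filtered, trailing "?"
## stripped (a surviving "term?" is treated as the bare term).
feature_tokens <- function(text, lexicon, target_terms) {
  toks <- filter_negated_tokens(tokenize(text), lexicon, target_terms)
  toks <- sub("\\?$", "", toks)
  toks[nzchar(toks)]
}
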