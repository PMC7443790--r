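# Deterministic Penn Treebank part-of-speech tagger.
#
# A lexicon of closed-class words and common open-class words, morphological
# suffix rules for unknown words, and two light context rules (base verbs
# after TO/modals; mid-sentence capitalized tokens as proper nouns).  The
# synthetic transcript generator draws from this same lexicon, so tags over
# synthetic data are exact ground truth.

#' The 36 Penn Treebank word-level tags
#'
#' Punctuation and symbol tags are not part of the analysis tagset; tokens
#' the tagger cannot place in this set are pooled into an \code{"other"}
#' bucket by \code{pos_tag_frequencies}.
#' @export
ptb_tagset <- function() {
  c("CC", "CD", "DT", "EX", "FW", "IN", "JJ", "JJR", "JJS", "LS", "MD",
    "NN", "NNS", "NNP", "NNPS", "PDT", "POS", "PRP", "PRP$", "RB", "RBR",
    "RBS", "RP", "SYM", "TO", "UH", "VB", "VBD", "VBG", "VBN", "VBP",
    "VBZ", "WDT", "WP", "WP$", "WRB")
}

# closed-class and frequent open-class lexicon (lowercase form -> tag);
# "verb_base" entries get VB after TO/MD, VBP otherwise
.lexicon <- local({
  lex <- list(
    DT = c("the", "a", "an", "this", "that", "these", "those", "each",
           "every", "some", "any", "all", "both", "no", "another"),
    PDT = c("such", "half"),
    CC = c("and", "or", "but", "nor", "yet", "so"),
    IN = c("in", "on", "at", "by", "with", "from", "of", "for", "about",
           "into", "over", "under", "after", "before", "during", "between",
           "through", "against", "without", "near", "since", "although",
           "because", "while", "if", "unless", "whereas", "until"),
    TO = "to",
    MD = c("can", "could", "will", "would", "shall", "should", "may",
           "might", "must"),
    PRP = c("i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
            "us", "them", "myself", "yourself", "himself", "herself",
            "itself", "ourselves", "themselves"),
    "PRP$" = c("my", "your", "his", "its", "our", "their"),
    EX = "there",
    WDT = "which",
    WP = c("who", "whom", "what"),
    "WP$" = "whose",
    WRB = c("when", "where", "why", "how"),
    UH = c("oh", "um", "uh", "wow", "hey", "yeah", "hmm", "ah", "okay",
           "gosh", "ouch"),
    RB = c("not", "very", "really", "quite", "too", "also", "just", "never",
           "always", "often", "sometimes", "here", "now", "then", "maybe",
           "perhaps", "again", "soon", "slowly", "quickly", "together"),
    CD = c("one", "two", "three", "four", "five", "six", "seven", "eight",
           "nine", "ten", "hundred", "thousand"),
    VBP = c("am", "are", "have", "do"),
    VBZ = c("is", "has", "does"),
    VBD = c("was", "were", "had", "did", "went", "sat", "said", "saw",
            "got", "made", "knew", "thought", "took", "came", "gave",
            "found", "told", "felt", "kept", "began", "brought", "ran",
            "ate", "spoke", "stood", "heard", "met", "left"),
    VBN = c("been", "done", "gone", "seen", "taken", "given", "known",
            "spoken", "written", "broken"),
    VBG = c("being", "having", "doing", "going"),
    JJ = c("good", "bad", "big", "small", "happy", "sad", "new", "old",
           "young", "long", "short", "high", "low", "nice", "strange",
           "quiet", "loud", "bright", "dark", "warm", "cold", "tired",
           "busy", "calm", "empty"),
    NN = c("time", "day", "home", "work", "school", "family", "friend",
           "house", "room", "street", "city", "music", "food", "water",
           "book", "story", "idea", "mind", "voice", "night", "morning",
           "cat", "dog", "car", "door", "window", "garden", "year",
           "week", "thing", "place", "people", "mother", "father",
           "sister", "brother", "doctor", "teacher", "kitchen", "phone"),
    verb_base = c("go", "see", "know", "think", "take", "come", "give",
                  "find", "tell", "feel", "keep", "begin", "bring", "run",
                  "eat", "speak", "stand", "hear", "meet", "want", "like",
                  "need", "try", "ask", "work", "play", "walk", "talk",
                  "look", "seem", "help", "start", "stop", "live", "move",
                  "stay", "remember", "forget", "say", "get", "make",
                  "leave", "sit", "pay")
  )
  out <- character(0)
  for (tag in names(lex)) out[lex[[tag]]] <- tag
  out
})

tag_token <- function(token, prev_tag, position) {
  low <- tolower(token)
  if (grepl("^[0-9]+([.,][0-9]+)?$", token)) return("CD")
  hit <- .lexicon[low]
  if (!is.na(hit)) {
    if (hit == "verb_base")
      return(if (!is.na(prev_tag) && prev_tag %in% c("TO", "MD")) "VB" else "VBP")
    return(unname(hit))
  }
  if (position > 1 && grepl("^[A-Z]", token))
    return(if (grepl("s$", token)) "NNPS" else "NNP")
  n <- nchar(low)
  if (n > 3 && grepl("ly$", low)) return("RB")
  if (n > 4 && grepl("ing$", low)) return("VBG")
  if (n > 3 && grepl("ed$", low)) return("VBD")
  if (n > 4 && grepl("est$", low)) return("JJS")
  if (n > 4 && grepl("(ous|ful|ive|able|al)$", low)) return("JJ")
  if (n > 5 && grepl("(tion|ment|ness|ity|ism)$", low)) return("NN")
  if (n > 3 && grepl("[^su]s$", low)) return("NNS")
  "NN"
}

#' Tag every token of a transcript
#'
#' @param t a \code{transcript} (original casing; the tagger is
#'   case-sensitive for proper nouns).
#' @return list of character vectors of tags, parallel to the sentences.
#' @export
pos_tag <- function(t) {
  stopifnot(inherits(t, "transcript"))
  lapply(t$sentences, function(toks) {
    tags <- character(length(toks))
    prev <- NA_character_
    for (i in seq_along(toks)) {
      tags[i] <- tag_token(toks[i], prev, i)
      prev <- tags[i]
    }
    tags
  })
}

#' Part-of-speech tag relative frequencies
#'
#' Each token receives exactly one tag; frequencies are counts divided by
#' the total token count.  Tags outside the configured tagset are pooled
#' into \code{"other"}; every configured tag appears in the output (0 when
#' absent), and the frequencies including \code{"other"} sum to 1.
#'
#' @param t a \code{transcript} with >= 1 token.
#' @param tagset character vector of tags to report (default: the 36 Penn
#'   Treebank word-level tags).
#' @return named numeric vector over \code{c(tagset, "other")}.
#' @export
pos_tag_frequencies <- function(t, tagset = ptb_tagset()) {
  tags <- unlist(pos_tag(t))
  if (length(tags) == 0) err("empty_transcript", "no tokens to tag")
  if (length(tagset) == 0 || anyDuplicated(tagset))
    err("tagger_unavailable", "tagset must be a non-empty set of distinct tags")
  tags[!tags %in% tagset] <- "other"
  lv <- c(tagset, "other")
  freq <- table(factor(tags, levels = lv)) / length(tags)
  stats::setNames(as.numeric(freq), lv)
}
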