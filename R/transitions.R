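#' Initial transcription state
#'
#' All compartments empty; for the minimal model the promoter starts (and
#' stays) occupied by a post-TFIIH polymerase.
#'
#' @param arch a [gene_architecture()].
#' @param gene_class gene class tag; determines whether a UAS flag exists
#'   and the minimal-model promoter convention.
#' @return An object of class `transcription_state` with fields
#'   `uas_occupied` (`NULL` when the architecture has no UAS),
#'   `promoter_state` (`"EMPTY"`, `"PRE"` or `"POST"`),
#'   `transcript_occupancy` (logical, one flag per bin),
#'   `terminator_occupied`, and `clock` (seconds).
#' @export
transcription_state <- function(arch, gene_class = c("TFO", "STM", "minimal")) {
  gene_class <- match.arg(gene_class)
  check_consistent(gene_class, arch)
  structure(list(
    uas_occupied = if (arch$has_uas) FALSE else NULL,
    promoter_state = if (gene_class == "minimal") "POST" else "EMPTY",
    transcript_occupancy = rep(FALSE, arch$n_transcript_bins),
    terminator_occupied = FALSE,
    clock = 0), class = "transcription_state")
}

check_consistent <- function(gene_class, arch, rates = NULL) {
  if (!is.null(rates) && rates$gene_class != gene_class)
    stop("rate set gene_class does not match")
  if (gene_class == "STM" && !arch$has_uas)
    stop("STM genes require an architecture with a UAS compartment")
  if (gene_class != "STM" && arch$has_uas)
    stop("UAS compartment on a ", gene_class, " gene")
  invisible(TRUE)
}

check_state <- function(state, arch) {
  if (length(state$transcript_occupancy) != arch$n_transcript_bins)
    stop("state transcript bins do not match the architecture")
  if (is.null(state$uas_occupied) != !arch$has_uas)
    stop("state UAS flag inconsistent with the architecture")
  if (!state$promoter_state %in% c("EMPTY", "PRE", "POST"))
    stop("invalid promoter state: ", state$promoter_state)
  invisible(TRUE)
}

#' Enumerate enabled transitions and their propensities
#'
#' The single source of truth for the model's transition structure, shared
#' by the pure-R reference simulator and the exact stationary oracle (the
#' compiled engine mirrors it and is cross-validated in the test suite).
#' Moves whose target compartment is occupied are absent from the returned
#' set (hard-core exclusion: zero propensity, not rejection sampling).
#' Promoter dissociation and reversal to the UAS are only possible before
#' TFIIH arrival; events using `k4`, `k5`, `k6` and `k7` are irreversible.
#'
#' @param state a [transcription_state()].
#' @param rates a [rate_set()] whose gene class matches the state.
#' @param arch a [gene_architecture()].
#' @return A data.frame with columns `event` and `propensity` (/s).  Event
#'   labels: `uas_recruit`, `uas_dissociate`, `uas_to_promoter`,
#'   `promoter_to_uas`, `promoter_recruit`, `promoter_dissociate`,
#'   `tfiih_arrival`, `initiation`, `hop_<i>` (bin i to its successor; the
#'   last hop enters the terminator), `terminator_release`.
#' @export
list_transitions <- function(state, rates, arch) {
  check_consistent(rates$gene_class, arch, rates)
  check_state(state, arch)
  cls <- rates$gene_class
  bins <- state$transcript_occupancy
  n <- length(bins)
  ev <- character(0); pr <- numeric(0)
  add <- function(e, p) { ev <<- c(ev, e); pr <<- c(pr, p) }

  if (cls == "STM") {
    if (!state$uas_occupied) add("uas_recruit", rates$k1)
    if (state$uas_occupied) {
      add("uas_dissociate", rates$k_rev1)
      if (state$promoter_state == "EMPTY") add("uas_to_promoter", rates$k2)
    }
    if (state$promoter_state == "PRE" && !state$uas_occupied)
      add("promoter_to_uas", rates$k_rev2)
  }
  if (cls == "TFO" && state$promoter_state == "EMPTY")
    add("promoter_recruit", rates$k3)
  if (cls != "minimal" && state$promoter_state == "PRE") {
    add("promoter_dissociate", rates$k_rev3)
    add("tfiih_arrival", rates$k4)
  }
  if (state$promoter_state == "POST" && !bins[1])
    add("initiation", rates$k5)
  khop <- rates$k6 / arch$compartment_length
  if (n > 1)
    for (i in seq_len(n - 1))
      if (bins[i] && !bins[i + 1]) add(paste0("hop_", i), khop)
  if (bins[n] && !state$terminator_occupied) add(paste0("hop_", n), khop)
  if (state$terminator_occupied) add("terminator_release", rates$k7)

  data.frame(event = ev, propensity = pr, stringsAsFactors = FALSE)
}

#' Apply a transition to a state
#'
#' @param state a [transcription_state()].
#' @param event an event label as returned by [list_transitions()].
#' @param gene_class gene class tag (the minimal model keeps its promoter
#'   occupied after initiation: instantaneous refill).
#' @return The successor `transcription_state` (clock unchanged; the
#'   simulator advances it separately).
#' @export
apply_event <- function(state, event, gene_class = c("TFO", "STM", "minimal")) {
  gene_class <- match.arg(gene_class)
  s <- state
  if (startsWith(event, "hop_")) {
    i <- as.integer(sub("hop_", "", event))
    n <- length(s$transcript_occupancy)
    if (!s$transcript_occupancy[i]) stop("hop from an empty bin")
    s$transcript_occupancy[i] <- FALSE
    if (i == n) {
      if (s$terminator_occupied) stop("exclusion violation at terminator")
      s$terminator_occupied <- TRUE
    } else {
      if (s$transcript_occupancy[i + 1]) stop("exclusion violation at bin ", i + 1)
      s$transcript_occupancy[i + 1] <- TRUE
    }
    return(s)
  }
  switch(event,
    uas_recruit = { s$uas_occupied <- TRUE; s },
    uas_dissociate = { s$uas_occupied <- FALSE; s },
    uas_to_promoter = {
      if (s$promoter_state != "EMPTY") stop("exclusion violation at promoter")
      s$uas_occupied <- FALSE; s$promoter_state <- "PRE"; s
    },
    promoter_to_uas = {
      if (s$uas_occupied) stop("exclusion violation at UAS")
      s$promoter_state <- "EMPTY"; s$uas_occupied <- TRUE; s
    },
    promoter_recruit = {
      if (s$promoter_state != "EMPTY") stop("exclusion violation at promoter")
      s$promoter_state <- "PRE"; s
    },
    promoter_dissociate = { s$promoter_state <- "EMPTY"; s },
    tfiih_arrival = { s$promoter_state <- "POST"; s },
    initiation = {
      if (s$transcript_occupancy[1]) stop("exclusion violation at bin 1")
      s$transcript_occupancy[1] <- TRUE
      s$promoter_state <- if (gene_class == "minimal") "POST" else "EMPTY"
      s
    },
    terminator_release = { s$terminator_occupied <- FALSE; s },
    stop("unknown event: ", event))
}
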