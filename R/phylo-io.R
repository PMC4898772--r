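#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is
#' the standard ape `"phylo"` object used throughout the package. Quoted
#' labels and `[...]` comments are handled by ape; internal node labels are
#' kept but never used in computation; a root edge, if present, is ignored.
#' Polytomies are preserved.
#'
#' @param file path to a Newick file (one tree).
#' @param text Newick string; exactly one of `file`/`text` must be given.
#' @param require_lengths if `TRUE` (default) every edge must carry a
#'   branch length; a missing length is an error naming the offending
#'   clade.
#' @return an object of class `"phylo"`.
#' @seealso [read_newick_trees()] for multi-tree files, [write_newick()].
#' @export
read_newick <- function(file = NULL, text = NULL, require_lengths = TRUE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'file' or 'text'")
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tr)) stop("Newick parse error: no tree found in input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("input contains ", length(tr),
           " trees; use read_newick_trees() for multi-tree input")
    tr <- tr[[1L]]
  }
  validate_phylo(tr, require_lengths = require_lengths)
  tr
}

#' Read a multi-tree Newick file (one tree per line)
#'
#' @inheritParams read_newick
#' @return a list of `"phylo"` objects (class `"multiPhylo"`).
#' @export
read_newick_trees <- function(file = NULL, text = NULL,
                              require_lengths = TRUE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'file' or 'text'")
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  text <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0L) stop("Newick parse error: no trees found in input")
  trees <- lapply(text, function(ln) read_newick(text = ln,
                                                 require_lengths = require_lengths))
  class(trees) <- "multiPhylo"
  trees
}

#' Serialize a phylogeny to Newick
#'
#' Branch lengths are written with 10 significant digits so that
#' `read_newick(write_newick(t))` round-trips within 1e-9 relative error.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to `file`).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylo(tree, require_lengths = FALSE)
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Validate the structural contract of a rooted tree
#'
#' Checks the invariants downstream code assumes: a single root, unique
#' non-empty tip labels, and non-negative branch lengths (present on every
#' edge when `require_lengths`).
#'
#' @inheritParams write_newick
#' @param require_lengths require a branch length on every edge.
#' @return the tree, invisibly.
#' @export
validate_phylo <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tips <- tree$tip.label
  if (any(!nzchar(tips))) stop("empty tip labels are not allowed")
  if (anyDuplicated(tips))
    stop("duplicate tip labels: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  ntot <- length(tips) + tree$Nnode
  kids <- tabulate(tree$edge[, 2L], nbins = ntot)
  roots <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  if (length(tips) > 1L && length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots))
  if (any(kids > 1L)) stop("a node has more than one parent")
  if (require_lengths) {
    if (is.null(tree$edge.length) ||
        length(tree$edge.length) != nrow(tree$edge) ||
        anyNA(tree$edge.length)) {
      bad <- if (is.null(tree$edge.length)) seq_len(nrow(tree$edge))
             else which(is.na(tree$edge.length))
      lab <- vapply(tree$edge[bad, 2L], function(n)
        if (n <= length(tips)) tips[n] else paste0("node_", n), "")
      stop("missing branch length on edge(s) to: ",
           paste(head(lab, 5L), collapse = ", "))
    }
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Read a phonotaxis trial table
#'
#' The trial table is the unit record of the playback experiment: one row
#' per trial with the tested population, the stimulus note count, the
#' stimulus mid-frequency in kHz, and the binary phonotactic response
#' (1 = approached the speaker, 0 = failed to recognize).
#'
#' @param file CSV path with header columns `population`, `stimulus_notes`,
#'   `stimulus_freq_khz`, `response`.
#' @return a validated `data.frame` with those four columns.
#' @export
read_trials_csv <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  validate_trials(d)
}

#' Validate a trial table against its contract
#'
#' @param trials data.frame with columns `population`, `stimulus_notes`,
#'   `stimulus_freq_khz`, `response`.
#' @return the validated data.frame (columns coerced to their types).
#' @export
validate_trials <- function(trials) {
  need <- c("population", "stimulus_notes", "stimulus_freq_khz", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(trials$response %in% c(0, 1)))
  if (length(bad))
    stop("non-binary response at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  if (any(!is.finite(trials$stimulus_freq_khz) | trials$stimulus_freq_khz <= 0))
    stop("stimulus_freq_khz must be positive at row(s): ",
         paste(head(which(!is.finite(trials$stimulus_freq_khz) |
                            trials$stimulus_freq_khz <= 0), 5L), collapse = ", "))
  nn <- trials$stimulus_notes
  if (any(!is.finite(nn) | nn < 1 | nn != round(nn)))
    stop("stimulus_notes must be positive integers at row(s): ",
         paste(head(which(!is.finite(nn) | nn < 1 | nn != round(nn)), 5L),
               collapse = ", "))
  trials$stimulus_notes <- as.integer(nn)
  trials$response <- as.integer(trials$response)
  trials$population <- as.character(trials$population)
  trials[need]
}

#' Read a tip trait table (population -> call note number)
#'
#' @param file CSV path with header columns `tip_label`, `state`.
#' @param S number of character states (default 4: one- to four-note calls).
#' @return a named integer vector of states keyed by tip label.
#' @export
read_traits_csv <- function(file, S = 4L) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(c("tip_label", "state"), names(d))
  if (length(miss))
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  st <- d$state
  if (any(!is.finite(st) | st < 1 | st > S | st != round(st)))
    stop("trait states must be integers in 1..", S)
  if (anyDuplicated(d$tip_label))
    stop("duplicate tip labels in trait table")
  setNames(as.integer(st), as.character(d$tip_label))
}

# Align a named state vector with a tree's tips; fail loudly on mismatch.
# Matching is exact and case-sensitive so data errors surface immediately.
match_tip_states <- function(tree, states, S = 4L) {
  if (is.null(names(states))) stop("tip states must be a named vector")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("no state for tree tip(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(states), tree$tip.label)
  if (length(extra))
    stop("trait table has label(s) absent from the tree: ",
         paste(extra, collapse = ", "))
  st <- states[tree$tip.label]
  if (any(!is.finite(st) | st < 1 | st > S | st != round(st)))
    stop("states must be integers in 1..", S)
  as.integer(st)
}
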