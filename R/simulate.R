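# Derive a component RNG seed from the global one. The global seed maps
# to a base stream; each named component gets base*100 + counter so the
# tree, the character and every population's trials are independently
# reproducible. Kept below 2^31 for R's 32-bit integer seeds.
component_seed <- function(seed, counter) {
  (abs(as.integer(seed)) %% 21000000L) * 100L + as.integer(counter)
}

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Forward simulation: two lineages at the root, exponential waiting times
#' between birth events at total rate (current lineages) x `birth_rate`,
#' a uniformly chosen lineage splitting at each event, and a final
#' waiting-time epoch (at `n_tips` lineages) before the present. All
#' tip-to-root path lengths are equal by construction.
#'
#' @param n_tips number of tips (`>= 2`).
#' @param birth_rate speciation rate per lineage per unit time (`> 0`).
#' @param tip_labels optional character vector of tip labels (length
#'   `n_tips`); default `t1..tn` in birth order.
#' @param seed optional seed applied with [set.seed()] before drawing.
#' @return a rooted binary ultrametric `"phylo"` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, tip_labels = NULL,
                               seed = NULL) {
  if (!is.finite(n_tips) || n_tips < 2 || n_tips != round(n_tips))
    stop("n_tips must be an integer >= 2")
  if (!is.finite(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n_tips <- as.integer(n_tips)
  # internal bookkeeping: node 1 = root (split time 0); children appended
  parent <- c(NA_integer_, 1L, 1L)
  split_time <- c(0, NA_real_, NA_real_)
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + rexp(1L, k * birth_rate)
    i <- active[sample.int(k, 1L)]
    split_time[i] <- t
    id <- length(parent) + c(1L, 2L)
    parent[id] <- i
    split_time[id] <- NA_real_
    active <- c(setdiff(active, i), id)
  }
  t_end <- t + rexp(1L, n_tips * birth_rate)
  end_time <- ifelse(is.na(split_time), t_end, split_time)
  start_time <- c(0, end_time[parent[-1L]])

  is_tip <- !(seq_along(parent) %in% parent)
  tips <- which(is_tip)
  ints <- which(!is_tip)
  newid <- integer(length(parent))
  newid[tips] <- seq_along(tips)
  newid[ints] <- length(tips) + seq_along(ints) # root (old id 1) first
  edge <- cbind(newid[parent[-1L]], newid[-1L])
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_along(tips))
  if (length(tip_labels) != n_tips) stop("tip_labels must have length n_tips")
  tr <- structure(list(edge = edge,
                       edge.length = (end_time - start_time)[-1L],
                       tip.label = tip_labels,
                       Nnode = length(ints)),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a discrete character under the ER Mk model (Gillespie)
#'
#' Evolves the character down the tree from `root_state`: along an edge,
#' waiting times to the next change are exponential with total rate
#' `(S-1) * q`, and each change jumps uniformly to one of the other
#' `S - 1` states. Every change event is recorded, giving the ground
#' truth for change-counting recovery tests.
#'
#' @param tree rooted `"phylo"` with branch lengths.
#' @param q transition rate (`>= 0`).
#' @param S number of states.
#' @param root_state state at the root (`1..S`).
#' @param seed optional seed.
#' @return list with `tip_states` (named vector), `node_states` (states
#'   at every node, ape numbering), and `changes` (data.frame: edge
#'   parent/child, from, to, position along the edge).
#' @export
simulate_mk_character <- function(tree, q, S = 4L, root_state = 1L,
                                  seed = NULL) {
  if (!is.finite(q) || q < 0) stop("rate q must be >= 0")
  if (!(root_state %in% seq_len(S))) stop("root_state must be in 1..S")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  tr <- if (ntip > 1L) ape::reorder.phylo(tree, "postorder") else tree
  ntot <- ntip + tree$Nnode
  node_states <- integer(ntot)
  node_states[ntip + 1L] <- as.integer(root_state)
  rate <- (S - 1) * q
  ev <- list()
  for (i in rev(seq_len(nrow(tr$edge)))) { # preorder
    par <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    s <- node_states[par]
    len <- tr$edge.length[i]
    if (rate > 0) {
      at <- 0
      repeat {
        w <- rexp(1L, rate)
        if (at + w > len) break
        at <- at + w
        new <- sample.int(S - 1L, 1L)
        new <- if (new >= s) new + 1L else new
        ev[[length(ev) + 1L]] <- data.frame(parent = par, child = ch,
                                            from = s, to = new,
                                            position = at)
        s <- new
      }
    }
    node_states[ch] <- s
  }
  changes <- if (length(ev)) do.call(rbind, ev)
             else data.frame(parent = integer(), child = integer(),
                             from = integer(), to = integer(),
                             position = numeric())
  list(tip_states = setNames(node_states[seq_len(ntip)], tree$tip.label),
       node_states = node_states, changes = changes)
}

#' Simulate binary phonotaxis trials for one population
#'
#' Stimulus frequencies are uniform on `center_freq +/- freq_halfwidth`,
#' note variants uniform over the tested set, and the response Bernoulli
#' with `logit p = logit_amplitude + note_offset(k) -
#' ((f - center_freq) / freq_scale)^2` — a smooth unimodal response
#' surface peaking at the population's own call frequency, with
#' note-dependent amplitude.
#'
#' @param population population label.
#' @param own_note the population's own note count.
#' @param center_freq own call frequency (kHz, `> 0`).
#' @param note_offsets named numeric vector of logit offsets, one per
#'   tested note variant (names = note counts; own variant conventionally
#'   0).
#' @param n_trials number of trials (`>= 20`).
#' @param logit_amplitude peak logit at the center frequency for a
#'   zero-offset variant.
#' @param freq_halfwidth half-range of tested frequencies (kHz).
#' @param freq_scale width of the unimodal response (kHz).
#' @param seed optional seed.
#' @return list with `trials` (a trial-table data.frame) and `truth`
#'   (the generating parameters).
#' @export
simulate_trials <- function(population, own_note, center_freq,
                            note_offsets, n_trials,
                            logit_amplitude = 1.5,
                            freq_halfwidth = 0.25,
                            freq_scale = 0.15, seed = NULL) {
  if (n_trials < 20L) stop("n_trials must be >= 20")
  if (center_freq <= 0) stop("center_freq must be positive (kHz)")
  if (is.null(names(note_offsets)))
    stop("note_offsets must be named by note count")
  if (!is.null(seed)) set.seed(seed)
  variants <- as.integer(names(note_offsets))
  f <- runif(n_trials, center_freq - freq_halfwidth,
             center_freq + freq_halfwidth)
  k <- variants[sample.int(length(variants), n_trials, replace = TRUE)]
  eta <- logit_amplitude + note_offsets[as.character(k)] -
    ((f - center_freq) / freq_scale)^2
  y <- rbinom(n_trials, 1L, plogis(eta))
  trials <- data.frame(population = population, stimulus_notes = k,
                       stimulus_freq_khz = f, response = y)
  truth <- list(population = population, own_note = own_note,
                center_freq = center_freq, note_offsets = note_offsets,
                logit_amplitude = logit_amplitude,
                freq_halfwidth = freq_halfwidth, freq_scale = freq_scale,
                n_trials = n_trials)
  list(trials = trials, truth = truth)
}

# The study's design table: the eight playback populations with their own
# call note number, mean peak frequency (kHz), trial count, reported
# note-effect p-value and explained variance (%). Used both as the
# default synthetic design and by summarize/bookkeeping checks.
study_design <- function() {
  data.frame(
    population = c("Careiro", "Leticia", "Hileia", "Ducke",
                   "Panguana", "Catuaba", "Treviso", "Aratai"),
    own_note = c(4L, 4L, 4L, 4L, 3L, 2L, 4L, 4L),
    peak_freq_khz = c(3.12, 3.08, 3.10, 2.87, 3.07, 3.34, 3.33, 3.44),
    n_trials = c(72L, 67L, 89L, 73L, 72L, 72L, 80L, 68L),
    note_p = c(0.012, 0.043, 0.013, 0.025, 0.010, 0.452, 0.052, 0.010),
    explained_variance_pct = c(50.7, 60.0, 32.8, 57.7, 60.2, 34.4, 32.9,
                               44.5),
    stringsAsFactors = FALSE
  )
}

#' The playback study design table
#'
#' Eight Amazonian populations with their own call note number, mean peak
#' frequency, number of playback trials, and the published note-effect
#' p-value and explained variance. The N column sums to 593 trials.
#'
#' @return a data.frame with one row per population.
#' @export
playback_design <- function() study_design()

# Per-preset note-offset constructor. Offsets are logit shifts relative
# to the favored variant; distance-graded shifts of -1.5 per note step
# reproduce the clear but partial separation of the observed response
# curves. `favored` defaults to the own note; the decoupled preset favors
# the ancestral state instead for the note-shifted population.
preset_offsets <- function(preset, own_note, variants = c(2L, 3L, 4L),
                           ancestral_note = 4L) {
  off <- switch(preset,
    null = setNames(rep(0, length(variants)), variants),
    coupled = setNames(ifelse(variants == own_note, 0, -10), variants),
    intermediate = setNames(-1.5 * abs(variants - own_note), variants),
    decoupled = {
      if (own_note == ancestral_note) {
        setNames(-1.5 * abs(variants - own_note), variants)
      } else if (own_note == 3L) {
        # note-shifted population whose recognition still favors the
        # ancestral four-note call
        setNames(-1.5 * abs(variants - ancestral_note), variants)
      } else {
        # deeply diverged two-note population: flat response (null-like)
        setNames(rep(0, length(variants)), variants)
      }
    },
    stop("unknown preset '", preset, "'")
  )
  off
}

#' Generate a full synthetic study under a named evolutionary scenario
#'
#' Emits a complete dataset — tree, tip note states, phonotaxis trials and
#' generating truth — for the eight-population study design under one of
#' four scenario presets:
#'
#' * `"null"` — every population responds alike to all note variants.
#' * `"coupled"` — matched spaces: each population recognizes only its
#'   own variant.
#' * `"intermediate"` — own variant favored, foreign variants partially
#'   recognized (offsets graded by note distance).
#' * `"decoupled"` — note number has evolved while recognition lags: the
#'   three-note population's surface still favors the ancestral four-note
#'   call, the two-note population responds flat, the four-note
#'   populations are intermediate (the observed mixture).
#'
#' Populations carry the study's names, own note numbers and call
#' frequencies; trial counts are drawn from 67..89 per population (or set
#' exactly to the study's N column with `trial_counts = "design"`). The
#' single `seed` expands deterministically to per-component seeds.
#'
#' @param preset one of `"coupled"`, `"null"`, `"intermediate"`,
#'   `"decoupled"`.
#' @param seed integer seed fixing all randomness.
#' @param trial_counts `"random"` (drawn from 67..89) or `"design"`
#'   (exactly the study's per-population N).
#' @param birth_rate Yule rate for the tree.
#' @return an object of class `"call_study"`: list with `tree`, `traits`
#'   (named tip states), `trials` (combined trial table), `design`
#'   (per-population config), `truth` (per-population generating
#'   parameters), `preset`, `seed`.
#' @export
make_preset <- function(preset = c("coupled", "null", "intermediate",
                                   "decoupled"),
                        seed = 1L, trial_counts = c("random", "design"),
                        birth_rate = 1) {
  preset <- match.arg(preset)
  trial_counts <- match.arg(trial_counts)
  des <- study_design()
  n_pop <- nrow(des)
  tree <- simulate_yule_tree(n_pop, birth_rate = birth_rate,
                             tip_labels = des$population,
                             seed = component_seed(seed, 1L))
  traits <- setNames(des$own_note, des$population)
  set.seed(component_seed(seed, 2L))
  n_trials <- if (trial_counts == "design") des$n_trials
              else sample(67:89, n_pop, replace = TRUE)
  sims <- lapply(seq_len(n_pop), function(i) {
    simulate_trials(
      population = des$population[i],
      own_note = des$own_note[i],
      center_freq = des$peak_freq_khz[i],
      note_offsets = preset_offsets(preset, des$own_note[i]),
      n_trials = n_trials[i],
      seed = component_seed(seed, 2L + i)
    )
  })
  trials <- do.call(rbind, lapply(sims, `[[`, "trials"))
  rownames(trials) <- NULL
  des$n_trials <- n_trials
  out <- list(tree = tree, traits = traits, trials = trials,
              design = des,
              truth = lapply(sims, `[[`, "truth"),
              preset = preset, seed = seed)
  class(out) <- "call_study"
  out
}

#' @export
print.call_study <- function(x, ...) {
  cat("Synthetic call-recognition study (preset '", x$preset,
      "', seed ", x$seed, ")\n", sep = "")
  cat("  populations :", length(x$traits), "\n")
  cat("  trials      :", nrow(x$trials), "\n")
  cat("  note states :", paste(sort(unique(x$traits)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a synthetic study to disk in the package's input formats
#'
#' Emits exactly the files the readers consume: `tree.nwk` (Newick),
#' `traits.csv` (`tip_label,state`), `trials.csv` (trial table) and
#' `truth.json` (generating parameters).
#'
#' @param study a `"call_study"` from [make_preset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  write.csv(data.frame(tip_label = names(study$traits),
                       state = unname(study$traits)),
            file.path(dir, "traits.csv"), row.names = FALSE)
  write.csv(study$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(list(preset = study$preset, seed = study$seed,
                            truth = study$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
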