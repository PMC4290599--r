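#' Build one of the four G4 HMM topologies
#'
#' Constructs an HMM skeleton for the canonical G-quadruplex architecture:
#' four G-run blocks alternating with three loop blocks between silent
#' `begin` and `end` states.
#'
#' The four models differ in how finely G-run and loop lengths are resolved:
#' \describe{
#'   \item{Model 1}{2 G-states per run (minimum run length 2, the last
#'     G-state self-loops so longer runs are allowed); one self-looping loop
#'     state per loop, with a bypass edge so loops may be empty.}
#'   \item{Model 2}{as model 1 but 4 G-states per run (minimum run length 4),
#'     giving a sharper run-length distribution.}
#'   \item{Model 3}{runs as model 1; each loop is a chain of several loop
#'     states (3, 4 and 3 by default, alternating) in which every state may
#'     be entered directly and exited early and the last self-loops, so loop
#'     lengths are modeled in more detail while any length remains reachable.}
#'   \item{Model 4}{hybrid of models 2 and 3: 4 G-states per run and chained
#'     loop blocks.}
#' }
#'
#' G-state emissions are initialized at `P(G) = g_init` (0.9) rather than
#' clamped to 1, so Baum-Welch decides how strict a G-run is; `clamp_g = TRUE`
#' forces `P(G) = 1` as a structural zero on the other bases. `rigid_runs`
#' drops the within-run self-loops, fixing each run at exactly the block's
#' state count.
#'
#' @param model_id Integer in 1..4.
#' @param rigid_runs If `TRUE`, runs have fixed length (no self-loop on the
#'   last G-state of each run).
#' @param clamp_g If `TRUE`, G-states emit G with probability 1 (structural).
#' @param g_init Initial emission probability of G in G-states.
#' @param loop_states Integer vector of length 3: number of chained loop
#'   states per loop block in models 3 and 4 (default `c(3, 4, 3)`).
#' @return A `g4hmm` object with uniform topology-respecting initial
#'   transition probabilities and per-state `labels` (`"run1"`..`"run4"`,
#'   `"loop1"`..`"loop3"`).
#' @examples
#' m1 <- build_model(1)
#' min_emittable_length(m1)  # 8: four 2-G runs, loops may be empty
#' @export
build_model <- function(model_id, rigid_runs = FALSE, clamp_g = FALSE,
                        g_init = 0.9, loop_states = c(3L, 4L, 3L)) {
  if (!model_id %in% 1:4) stop("unknown model id: must be 1, 2, 3 or 4")
  if (g_init <= 0 || g_init > 1) stop("g_init must be in (0, 1]")
  run_len <- if (model_id %in% c(2L, 4L)) 4L else 2L
  loops <- if (model_id %in% c(3L, 4L)) as.integer(loop_states)
           else c(1L, 1L, 1L)
  if (length(loops) != 3L || any(loops < 1L))
    stop("loop_states must be 3 positive integers")

  run_states <- lapply(1:4, function(k) sprintf("run%d.G%d", k, seq_len(run_len)))
  loop_states_nm <- lapply(1:3, function(k) sprintf("loop%d.N%d", k, seq_len(loops[k])))
  states <- c("begin",
              run_states[[1]], loop_states_nm[[1]],
              run_states[[2]], loop_states_nm[[2]],
              run_states[[3]], loop_states_nm[[3]],
              run_states[[4]], "end")
  m <- length(states)
  trans <- matrix(0, m, m, dimnames = list(states, states))
  edge <- function(from, to) trans[from, to] <<- 1

  edge("begin", run_states[[1]][1])
  for (k in 1:4) {
    rs <- run_states[[k]]
    for (i in seq_len(run_len - 1L)) edge(rs[i], rs[i + 1L])
    if (!rigid_runs) edge(rs[run_len], rs[run_len])
    last <- rs[run_len]
    if (k < 4L) {
      ls <- loop_states_nm[[k]]
      nxt <- run_states[[k + 1L]][1]
      edge(last, nxt)                      # empty-loop bypass
      for (s in ls) edge(last, s)          # enter the loop at any state
      L <- length(ls)
      for (i in seq_len(L)) {
        if (i < L) edge(ls[i], ls[i + 1L]) # chain
        edge(ls[i], nxt)                   # exit early
      }
      edge(ls[L], ls[L])                   # last loop state self-loops
    } else {
      edge(last, "end")
    }
  }
  out_deg <- rowSums(trans)
  trans[out_deg > 0, ] <- trans[out_deg > 0, , drop = FALSE] / out_deg[out_deg > 0]

  emis <- matrix(0, m, 4, dimnames = list(states, DNA_BASES))
  labels <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    s <- states[i]
    if (s %in% c("begin", "end")) next
    labels[i] <- sub("\\..*$", "", s)
    if (grepl("\\.G", s)) {
      if (clamp_g) emis[i, ] <- c(0, 0, 1, 0)
      else emis[i, ] <- ifelse(DNA_BASES == "G", g_init, (1 - g_init) / 3)
    } else {
      emis[i, ] <- 0.25
    }
  }
  hmm(trans, emis, labels = labels, model_id = as.integer(model_id))
}

#' Shortest sequence length the topology can emit
#'
#' Length of the shortest begin-to-end emission the model's transition graph
#' allows; sequences shorter than this can be rejected before running any
#' dynamic program. Computed by a shortest-path relaxation over the state
#' graph (self-loops can never shorten a path and are ignored).
#'
#' @param model A `g4hmm` object.
#' @return Integer minimum emittable length (e.g. 8 for model 1, 16 for
#'   model 2).
#' @export
min_emittable_length <- function(model) {
  m <- nrow(model$trans)
  dist <- rep(Inf, m)
  dist[1] <- 0
  # all topology edges except self-loops point forward in state order, so one
  # sweep in index order suffices
  for (s in seq_len(m - 1L)) {
    if (!is.finite(dist[s])) next
    for (t in which(model$trans[s, ] > 0)) {
      if (t == s) next
      cost <- if (t < m) 1L else 0L  # emitting states cost one base
      if (dist[s] + cost < dist[t]) dist[t] <- dist[s] + cost
    }
  }
  as.integer(dist[m])
}

#' Annotate a sequence with G-run/loop structure
#'
#' Viterbi-decodes `seq` under a G4 model and translates the state path into
#' per-base structural labels (`run1`..`run4`, `loop1`..`loop3`) and a region
#' table. Sequences with no admissible path yield an explicit unannotatable
#' result rather than an error.
#'
#' @param model A `g4hmm` built by [build_model()] (possibly trained).
#' @param seq A DNA string.
#' @return An object of class `g4_annotation`: list with `seq`, `labels`
#'   (per-base character vector), `regions` (data frame with `name`, `start`,
#'   `end` in 0-based half-open coordinates), `log_prob`, and `no_path`.
#' @export
annotate_g4 <- function(model, seq) {
  if (is.null(model$labels)) stop("model carries no state labels; build it with build_model()")
  vit <- hmm_viterbi(model, seq)
  if (vit$no_path)
    return(structure(list(seq = seq, labels = NULL,
                          regions = data.frame(name = character(0),
                                               start = integer(0),
                                               end = integer(0)),
                          log_prob = -Inf, no_path = TRUE),
                     class = "g4_annotation"))
  labels <- model$labels[vit$state_idx]
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  regions <- data.frame(name = r$values, start = ends - r$lengths, end = ends)
  structure(list(seq = seq, labels = labels, regions = regions,
                 log_prob = vit$log_prob, no_path = FALSE),
            class = "g4_annotation")
}

#' @export
print.g4_annotation <- function(x, ...) {
  if (x$no_path) {
    cat("<g4_annotation> unannotatable: no admissible path\n")
  } else {
    cat(sprintf("<g4_annotation> %d bases, %d regions, log-prob %.4f\n",
                nchar(x$seq), nrow(x$regions), x$log_prob))
    print(x$regions)
  }
  invisible(x)
}

#' Per-base in-G-run indicator from an annotation
#'
#' A base is predicted to lie in a G-run iff its Viterbi state belongs to a
#' run block. Unannotatable sequences give all-`FALSE` (no predictions).
#'
#' @param annotation A `g4_annotation`.
#' @return Logical vector, one element per base.
#' @export
in_run <- function(annotation) {
  if (annotation$no_path) return(rep(FALSE, nchar(annotation$seq)))
  startsWith(annotation$labels, "run")
}

#' Write G4 annotations to BED6 and per-base TSV
#'
#' @param annotation A `g4_annotation`.
#' @param seqid Sequence name for the BED `chrom` column.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the region table (0-based half-open).
#' @export
write_annotation <- function(annotation, seqid, bed_path = NULL, tsv_path = NULL) {
  reg <- annotation$regions
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = seqid, start = reg$start, end = reg$end,
                      name = reg$name, score = 0, strand = "+")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path) && !annotation$no_path) {
    perbase <- data.frame(seqid = seqid,
                          pos = seq_len(nchar(annotation$seq)) - 1L,
                          base = strsplit(annotation$seq, "")[[1]],
                          label = annotation$labels)
    write.table(perbase, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(reg)
}
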