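# Synthetic study generator: random small organic molecular graphs written
# as valid V2000 molfiles, a multi-level pathway hierarchy, and annotations
# in which pathway membership correlates with planted substructure motifs.
#
# The planted signal works like this: background molecules are random
# trees/rings over C/N/O only; every pathway owns a motif, a small star
# fragment centered on an S or P atom.  Because S and P never occur in the
# background, the radius-1 color of a motif's center atom occurs in a
# molecule exactly when the motif was embedded, so motif carriage is
# readable from the radius-1 features and the annotation signal is
# learnable by construction.  Embedding attaches the motif through a leaf
# atom, which leaves the center's radius-1 neighborhood untouched.

#' Configuration for the synthetic study generator
#'
#' Defaults describe the standard benchmark used throughout the package's
#' evaluation: 200 compounds, 50 pathways in a 7-deep hierarchy (so every
#' display level L1..L6+ is populated), annotation signal 0.95 and a 0.01
#' per-compound spurious-annotation rate.
#'
#' @param n_compounds,n_pathways Positive integers.
#' @param hierarchy_depth Depth of the pathway hierarchy, 1..9.
#' @param signal_strength Probability that a motif-carrying compound is
#'   annotated to the motif's pathway.
#' @param noise_rate Probability, per compound, of adding one spurious
#'   annotation to a uniformly random pathway.
#' @param seed Integer seed; the three generators draw from derived streams
#'   (`seed`, `seed + 1`, `seed + 2`) so the corpus is fully reproducible.
#' @param atom_range Heavy-atom count range per molecule (motif included).
#' @param second_motif_prob Per-draw probability of adding an extra,
#'   randomly chosen motif to a compound beyond its assigned one (up to
#'   `extra_motifs_max` draws).
#' @param extra_motifs_max Maximum number of extra motif draws per
#'   compound.
#' @param ring_prob Probability of closing one ring in the background tree.
#' @param elem_probs Sampling weights of C, N, O for background atoms.  The
#'   default keeps the background scaffold carbon-dominated so the
#'   background color vocabulary stays compact relative to the planted
#'   motif colors.
#' @param double_bond_prob Probability a background bond has order 2.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 200L, n_pathways = 50L,
                         hierarchy_depth = 7L, signal_strength = 0.95,
                         noise_rate = 0.01, seed = 1L,
                         atom_range = c(3L, 30L), second_motif_prob = 0.3,
                         extra_motifs_max = 1L, ring_prob = 0.25,
                         elem_probs = c(1, 0, 0), double_bond_prob = 0) {
  stopifnot(n_compounds >= 1L, n_pathways >= 1L,
            hierarchy_depth >= 1L, hierarchy_depth <= 9L,
            signal_strength >= 0, signal_strength <= 1,
            noise_rate >= 0, noise_rate <= 1,
            length(atom_range) == 2L, atom_range[1L] >= 3L,
            atom_range[1L] <= atom_range[2L],
            second_motif_prob >= 0, second_motif_prob <= 1,
            extra_motifs_max >= 0L, ring_prob >= 0, ring_prob <= 1,
            length(elem_probs) == 3L, all(elem_probs >= 0),
            sum(elem_probs) > 0,
            double_bond_prob >= 0, double_bond_prob <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_pathways = as.integer(n_pathways),
                 hierarchy_depth = as.integer(hierarchy_depth),
                 signal_strength = signal_strength, noise_rate = noise_rate,
                 seed = as.integer(seed),
                 atom_range = as.integer(atom_range),
                 second_motif_prob = second_motif_prob,
                 extra_motifs_max = as.integer(extra_motifs_max),
                 ring_prob = ring_prob, elem_probs = elem_probs,
                 double_bond_prob = double_bond_prob),
            class = "synth_config")
}

# Degree caps per element: no valence model, just enough realism to keep
# the generated connection tables plausible.
.degree_cap <- function(elem) {
  switch(elem, C = 4L, N = 4L, O = 2L, S = 2L, P = 4L, H = 1L, 4L)
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Deterministic motif set
#'
#' Enumerates small star fragments -- a center atom (S with 2 neighbors, or
#' P with 2 or 3 neighbors) bonded to leaves drawn from C/N/O with bond
#' order 1 or 2 -- in a fixed lexicographic order and returns the first `n`.
#' Distinct motifs have distinct center neighborhoods, so their radius-1
#' center colors are pairwise distinct, and S/P are reserved for motifs so
#' the colors are unique in any generated corpus.
#'
#' @param n Number of motifs (at most 98 under this enumeration).
#' @return A list of [molecule_graph()] fragments; atom 1 is the center.
#' @export
gen_motifs <- function(n) {
  n <- as.integer(n)
  # neighbor tokens in fixed order: (order, element)
  tok <- expand.grid(elem = c("C", "N", "O"), order = 1:2,
                     stringsAsFactors = FALSE)
  tok <- tok[order(tok$order, tok$elem), ]
  nt <- nrow(tok)
  specs <- list()
  # multisets of size 2, centers S then P
  for (center in c("S", "P")) {
    for (i in seq_len(nt)) for (j in i:nt) {
      specs[[length(specs) + 1L]] <- list(center = center, picks = c(i, j))
    }
  }
  # multisets of size 3, center P only (S is capped at degree 2)
  for (i in seq_len(nt)) for (j in i:nt) for (k in j:nt) {
    specs[[length(specs) + 1L]] <- list(center = "P", picks = c(i, j, k))
  }
  if (n > length(specs)) {
    stop("config error: at most ", length(specs),
         " distinct motifs are available", call. = FALSE)
  }
  lapply(seq_len(n), function(m) {
    sp <- specs[[m]]
    k <- length(sp$picks)
    molecule_graph(sprintf("MOTIF%02d", m),
                   c(sp$center, tok$elem[sp$picks]),
                   bonds = cbind(1L, 1L + seq_len(k), tok$order[sp$picks]))
  })
}

#' Radius-1 color signature of a motif's center atom
#'
#' The color that marks a molecule as carrying the motif; see
#' [color_atoms()] for the encoding.
#'
#' @param motif A motif graph from [gen_motifs()].
#' @return A single color string.
#' @export
motif_signature <- function(motif) {
  color_atoms(motif, 1L)[[2L]][1L]
}

# Which motifs each compound carries: a deterministic round-robin primary
# motif guarantees every pathway several carriers; additional random motifs
# add the membership overlap real pathway corpora show.  Consumes RNG,
# callers seed.
.draw_motif_sets <- function(config) {
  lapply(seq_len(config$n_compounds), function(i) {
    mots <- (i - 1L) %% config$n_pathways + 1L
    n_extra <- stats::rbinom(1L, config$extra_motifs_max,
                             config$second_motif_prob)
    if (n_extra > 0L) {
      mots <- unique(c(mots, sample.int(config$n_pathways, n_extra)))
    }
    mots
  })
}

#' Generate the synthetic molecule corpus
#'
#' Each compound is a random background tree over C/N/O (bond orders 1-2,
#' optional single ring closure, element degree caps 4/4/2) with its
#' assigned motif(s) attached through a motif leaf.  Total heavy-atom
#' counts stay within `config$atom_range`.  Output is byte-reproducible
#' from the seed.
#'
#' @param config A [synth_config()].
#' @return A named character vector of V2000 molfile strings (names are the
#'   compound IDs), with attribute `"motifs"`: a list of the motif indices
#'   planted in each compound.
#' @export
gen_molecules <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  motifs <- gen_motifs(config$n_pathways)
  msizes <- vapply(motifs, function(m) length(m$elements), integer(1L))
  carried <- .draw_motif_sets(config)
  lo <- config$atom_range[1L]; hi <- config$atom_range[2L]
  out <- character(config$n_compounds)
  ids <- sprintf("CPD%04d", seq_len(config$n_compounds))
  for (i in seq_len(config$n_compounds)) {
    mt <- carried[[i]]
    mtot <- sum(msizes[mt])
    if (hi - mtot < 1L) {
      stop("config error: motif payload (", mtot,
           " atoms) leaves no room within atom_range", call. = FALSE)
    }
    nb <- .sample1(max(1L, lo - mtot):(hi - mtot))
    elems <- sample(c("C", "N", "O"), nb, replace = TRUE,
                    prob = config$elem_probs)
    deg <- integer(nb)
    bonds <- matrix(integer(0), 0L, 3L)
    if (nb >= 2L) {
      for (a in 2:nb) {
        prev <- seq_len(a - 1L)
        open <- prev[deg[prev] < vapply(elems[prev], .degree_cap,
                                        integer(1L))]
        parent <- if (length(open)) .sample1(open) else
          prev[which.min(deg[prev])]
        ord <- if (stats::runif(1L) < config$double_bond_prob) 2L else 1L
        bonds <- rbind(bonds, c(parent, a, ord))
        deg[parent] <- deg[parent] + 1L
        deg[a] <- deg[a] + 1L
      }
      if (nb >= 4L && stats::runif(1L) < config$ring_prob) {
        cand <- which(elems == "C" & deg < 4L)
        if (length(cand) >= 2L) {
          pick <- sample(cand, 2L)
          adjacent <- any((bonds[, 1L] == pick[1L] & bonds[, 2L] == pick[2L]) |
                          (bonds[, 1L] == pick[2L] & bonds[, 2L] == pick[1L]))
          if (!adjacent) {
            bonds <- rbind(bonds, c(pick[1L], pick[2L], 1L))
            deg[pick] <- deg[pick] + 1L
          }
        }
      }
    }
    for (m in mt) {
      mo <- motifs[[m]]
      off <- length(elems)
      elems <- c(elems, mo$elements)
      deg <- c(deg, integer(length(mo$elements)))
      mb <- mo$bonds
      mb[, 1L] <- mb[, 1L] + off
      mb[, 2L] <- mb[, 2L] + off
      bonds <- rbind(bonds, mb)
      for (r in seq_len(nrow(mo$bonds))) {
        deg[mb[r, 1L]] <- deg[mb[r, 1L]] + 1L
        deg[mb[r, 2L]] <- deg[mb[r, 2L]] + 1L
      }
      # attach through the least-connected leaf; never through the center,
      # whose radius-1 color is the motif signature
      leaves <- off + 2:length(mo$elements)
      leaf <- leaves[which.min(deg[leaves])]
      bg_open <- which(seq_along(elems) <= off &
                       deg < vapply(elems, .degree_cap, integer(1L)))
      bg_open <- bg_open[bg_open <= off]
      anchor <- if (length(bg_open)) .sample1(bg_open) else
        which.min(deg[seq_len(off)])
      bonds <- rbind(bonds, c(anchor, leaf, 1L))
      deg[anchor] <- deg[anchor] + 1L
      deg[leaf] <- deg[leaf] + 1L
    }
    out[i] <- write_molfile(molecule_graph(ids[i], elems, bonds = bonds))
  }
  names(out) <- ids
  attr(out, "motifs") <- carried
  out
}

#' Generate a synthetic pathway hierarchy
#'
#' Pathway IDs are spread over levels `1..hierarchy_depth` round-robin (so
#' every requested level is populated); each non-root draws one parent --
#' and, occasionally, a second parent -- from the level directly above, so
#' the minimum-depth level of every node equals its assigned level and the
#' graph is acyclic by construction.
#'
#' @param config A [synth_config()].
#' @return A list with `hierarchy` ([pathway_hierarchy()]) and `levels`
#'   ([assign_levels()] map covering all pathways).
#' @export
gen_hierarchy <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n <- config$n_pathways
  ids <- sprintf("PW%03d", seq_len(n))
  depth <- min(config$hierarchy_depth, n)
  lvl <- sort(rep_len(seq_len(depth), n))
  parent <- character(0); child <- character(0)
  for (i in seq_len(n)) {
    if (lvl[i] == 1L) next
    above <- ids[lvl == lvl[i] - 1L]
    p1 <- .sample1(above)
    parent <- c(parent, p1); child <- c(child, ids[i])
    if (length(above) > 1L && stats::runif(1L) < 0.15) {
      p2 <- .sample1(setdiff(above, p1))
      parent <- c(parent, p2); child <- c(child, ids[i])
    }
  }
  hier <- pathway_hierarchy(parent, child)
  list(hierarchy = hier, levels = assign_levels(hier, ids = ids))
}

# Transitive ancestor sets of every node in a hierarchy (memoized walk up
# the parent map; the constructor guarantees acyclicity).
.ancestor_sets <- function(hierarchy) {
  parent_of <- split(hierarchy$edges$parent, hierarchy$edges$child)
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- parent_of[[id]]
    out <- if (is.null(ps)) character(0) else
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[id]] <- out
    out
  }
  nodes <- unique(c(hierarchy$edges$parent, hierarchy$edges$child))
  stats::setNames(lapply(nodes, anc), nodes)
}

#' Generate annotations correlated with the planted motifs
#'
#' Pathway `j` owns motif `j`.  Motif carriage is detected from the
#' molecules themselves (the motif's radius-1 center color, see
#' [motif_signature()]); each carrier is annotated to the motif's pathway
#' with probability `signal_strength`, and each compound gains one spurious
#' annotation to a uniformly random pathway with probability `noise_rate`.
#' Annotations then propagate to all ancestor pathways in the hierarchy,
#' mirroring how pathway knowledgebases list a compound under every
#' pathway containing the event it takes part in; higher-level pathways
#' therefore accumulate the members (and sizes) of their subtrees.
#'
#' @param config A [synth_config()].
#' @param molecules Output of [gen_molecules()] (molfile strings).
#' @param hierarchy A [pathway_hierarchy()] used for ancestor propagation;
#'   `NULL` disables propagation.
#' @param seed RNG seed, default `config$seed + 2` so annotations can be
#'   re-drawn over the same corpus.
#' @return An [annotation_table()] (possibly empty when
#'   `signal_strength = 0` and `noise_rate = 0`), with attribute
#'   `"prevalence"` = pairs / (compounds x pathways).
#' @export
gen_annotations <- function(config, molecules, hierarchy = NULL,
                            seed = config$seed + 2L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(seed))
  sigs <- vapply(gen_motifs(config$n_pathways), motif_signature,
                 character(1L))
  pids <- sprintf("PW%03d", seq_len(config$n_pathways))
  cp <- character(0); pw <- character(0)
  for (cid in names(molecules)) {
    g <- strip_hydrogens(parse_molfile(molecules[[cid]], compound_id = cid))
    have <- unique(unlist(color_atoms(g, 1L)))
    for (j in which(sigs %in% have)) {
      if (stats::runif(1L) < config$signal_strength) {
        cp <- c(cp, cid); pw <- c(pw, pids[j])
      }
    }
    if (stats::runif(1L) < config$noise_rate) {
      cp <- c(cp, cid); pw <- c(pw, .sample1(pids))
    }
  }
  if (!is.null(hierarchy) && length(cp)) {
    anc <- .ancestor_sets(hierarchy)
    extra_cp <- character(0); extra_pw <- character(0)
    for (k in seq_along(cp)) {
      up <- anc[[pw[k]]]
      if (length(up)) {
        extra_cp <- c(extra_cp, rep(cp[k], length(up)))
        extra_pw <- c(extra_pw, up)
      }
    }
    cp <- c(cp, extra_cp); pw <- c(pw, extra_pw)
  }
  ann <- annotation_table(cp, pw)
  attr(ann, "prevalence") <-
    nrow(ann) / (config$n_compounds * config$n_pathways)
  ann
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [gen_molecules()], [gen_hierarchy()], and
#' [gen_annotations()] and parsing the molfiles.
#'
#' @param config A [synth_config()].
#' @return A list with `molfiles`, `graphs`, `hierarchy`, `levels`, and
#'   `annotations`.
#' @export
synth_study <- function(config = synth_config()) {
  mols <- gen_molecules(config)
  hier <- gen_hierarchy(config)
  ann <- gen_annotations(config, mols, hier$hierarchy)
  graphs <- lapply(names(mols), function(id)
    parse_molfile(mols[[id]], compound_id = id))
  list(molfiles = mols, graphs = graphs, hierarchy = hier$hierarchy,
       levels = hier$levels, annotations = ann)
}

#' Write a synthetic study to disk
#'
#' Emits one molfile per compound (`<id>.mol`), an annotation TSV
#' (`annotations.tsv`, pathway then compound), and a hierarchy TSV
#' (`hierarchy.tsv`, parent then child) into `dir`.
#'
#' @param study A [synth_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$molfiles)) {
    writeLines(sub("\n$", "", study$molfiles[[id]]),
               file.path(dir, paste0(id, ".mol")))
  }
  ann <- study$annotations
  writeLines(paste(ann$pathway_id, ann$compound_id, sep = "\t"),
             file.path(dir, "annotations.tsv"))
  ed <- study$hierarchy$edges
  writeLines(paste(ed$parent, ed$child, sep = "\t"),
             file.path(dir, "hierarchy.tsv"))
  invisible(dir)
}
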