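#' Default mosaic domain architecture
#'
#' The LSU gene is a mosaic of conserved cores interleaved with divergent
#' (expansion) domains. The default architecture spans 3,396 bp with 12
#' divergent domains separated by 13 conserved segments, echoing the classic
#' divergent-domain map of the eukaryote LSU gene. Per-branch substitution
#' probabilities default to 0.001 (conserved) and 0.02 (divergent); these are
#' configurable stand-ins, not measured rates.
#'
#' @param conserved_rate,divergent_rate Per-site, per-branch substitution
#'   probabilities before rank multipliers are applied.
#' @return Data frame with columns \code{start}, \code{end}, \code{class},
#'   \code{rate} (1-based inclusive coordinates).
#' @export
default_architecture <- function(conserved_rate = 0.001,
                                 divergent_rate = 0.02) {
  seg <- rbind(
    c(1, 150, "conserved"),    c(151, 420, "divergent"),
    c(421, 560, "conserved"),  c(561, 630, "divergent"),
    c(631, 700, "conserved"),  c(701, 900, "divergent"),
    c(901, 1020, "conserved"), c(1021, 1180, "divergent"),
    c(1181, 1500, "conserved"), c(1501, 1650, "divergent"),
    c(1651, 1750, "conserved"), c(1751, 1900, "divergent"),
    c(1901, 2000, "conserved"), c(2001, 2150, "divergent"),
    c(2151, 2250, "conserved"), c(2251, 2400, "divergent"),
    c(2401, 2500, "conserved"), c(2501, 2680, "divergent"),
    c(2681, 2780, "conserved"), c(2781, 2930, "divergent"),
    c(2931, 3030, "conserved"), c(3031, 3180, "divergent"),
    c(3181, 3250, "conserved"), c(3251, 3330, "divergent"),
    c(3331, 3396, "conserved"))
  out <- data.frame(start = as.integer(seg[, 1]), end = as.integer(seg[, 2]),
                    class = seg[, 3], stringsAsFactors = FALSE)
  out$rate <- ifelse(out$class == "divergent", divergent_rate, conserved_rate)
  out
}

#' Simulation configuration
#'
#' Bundles everything the reference-database generator needs: a balanced
#' taxonomy shape, the domain architecture, the primer layout (each primer
#' anchored inside a conserved segment), per-rank branch-length multipliers,
#' and the substitution rate inside primer-binding sites.
#'
#' Rank multipliers scale per-branch substitution probabilities so divergence
#' accumulates toward the root: sequences within a genus stay cohesive while
#' phyla are well separated.
#'
#' @param counts Named integer vector: number of phyla, classes per phylum,
#'   orders per class, families per order, genera per family, species per
#'   genus. All must be >= 1.
#' @param seqs_per_species Records emitted per species leaf.
#' @param architecture Domain architecture ([default_architecture()] layout).
#' @param primers Data frame (name, seq, orientation, site_start) placing each
#'   primer's binding site on the architecture; reverse-orientation primers
#'   are planted as reverse complements.
#' @param site_rate Per-branch substitution probability inside primer sites
#'   (more conserved than ordinary conserved sequence - that is what makes a
#'   usable primer site).
#' @param multipliers Named numeric vector of per-rank branch multipliers
#'   (branch leading to a node of that rank).
#' @param record_multiplier Branch multiplier for within-species record
#'   branches (used when \code{seqs_per_species > 1}).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(counts = c(phyla = 2, classes = 2, orders = 2,
                                  families = 2, genera = 2, species = 2),
                       seqs_per_species = 1,
                       architecture = default_architecture(),
                       primers = default_sim_primers(),
                       site_rate = 5e-4,
                       multipliers = c(kingdom = 4, phylum = 3, class = 2.5,
                                       order = 2, family = 1.5, genus = 1.2,
                                       species = 1),
                       record_multiplier = 0.5) {
  need <- c("phyla", "classes", "orders", "families", "genera", "species")
  stopifnot(all(need %in% names(counts)))
  counts <- counts[need]
  if (any(counts < 1) || seqs_per_species < 1) {
    stop("all taxon counts and seqs_per_species must be >= 1")
  }
  stopifnot(identical(names(multipliers), tax_ranks()))
  len <- max(architecture$end)
  if (any(architecture$start[-1] != architecture$end[-nrow(architecture)] + 1) ||
      architecture$start[[1]] != 1) {
    stop("architecture segments must tile 1..L contiguously")
  }
  if (any(architecture$rate[architecture$class == "divergent"] <=
          max(architecture$rate[architecture$class == "conserved"]))) {
    stop("divergent substitution rates must exceed conserved rates")
  }
  for (i in seq_len(nrow(primers))) {
    s <- primers$site_start[[i]]
    e <- s + nchar(primers$seq[[i]]) - 1L
    if (e > len) stop("primer ", primers$name[[i]],
                      " extends past the architecture")
    seg <- which(architecture$start <= s & architecture$end >= e)
    if (length(seg) == 0 || architecture$class[[seg[1]]] != "conserved") {
      stop("primer ", primers$name[[i]],
           " is not anchored inside a single conserved segment")
    }
  }
  structure(list(counts = counts, seqs_per_species = seqs_per_species,
                 architecture = architecture, primers = primers,
                 site_rate = site_rate, multipliers = multipliers,
                 record_multiplier = record_multiplier, length = len),
            class = "sim_config")
}

#' Default simulated primer layout
#'
#' The four 5' LSU primers used throughout the benchmark (LR0R, LR3, LR5,
#' LR7), planted at their published coordinates on the 3,396 bp default
#' architecture. LR0R is a forward primer; the others are reverse primers
#' whose reverse complements occupy the stated sites.
#'
#' @return Data frame (name, seq, orientation, site_start).
#' @export
default_sim_primers <- function() {
  p <- lsu_primers()
  p <- p[p$name %in% c("LR0R", "LR3", "LR5", "LR7"), ]
  data.frame(name = p$name, seq = p$seq, orientation = p$orientation,
             site_start = pmin(p$ref_start, p$ref_end),
             stringsAsFactors = FALSE)
}

#' Generate a balanced taxonomy
#'
#' Builds the balanced rank tree described by a configuration: one kingdom
#' ("Fungi"), then the configured number of children at each rank. Node names
#' encode the path (e.g. genus \code{G1.2.1.2.1}), so names are unique per
#' (rank, parent).
#'
#' @param config A [sim_config()].
#' @return A [build_taxonomy()] object with
#'   \code{prod(counts)} species leaves.
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$counts
  prefixes <- c("P", "C", "O", "F", "G", "S")
  grid <- expand.grid(lapply(unname(counts), seq_len))
  lin <- matrix(NA_character_, nrow(grid), 7,
                dimnames = list(NULL, tax_ranks()))
  lin[, "kingdom"] <- "Fungi"
  for (d in 1:6) {
    path <- apply(grid[, seq_len(d), drop = FALSE], 1, paste, collapse = ".")
    lin[, d + 1L] <- paste0(prefixes[[d]], path)
  }
  build_taxonomy(lin)
}

# integer <-> base conversions for sequences (1=A 2=C 3=G 4=T)
BASES <- c("A", "C", "G", "T")
seq_to_int <- function(s) match(chars(s), BASES)
int_to_seq <- function(v) paste(BASES[v], collapse = "")

# per-position substitution probability implied by architecture + primer sites
position_rates <- function(config) {
  rates <- numeric(config$length)
  for (i in seq_len(nrow(config$architecture))) {
    rates[config$architecture$start[[i]]:config$architecture$end[[i]]] <-
      config$architecture$rate[[i]]
  }
  for (i in seq_len(nrow(config$primers))) {
    s <- config$primers$site_start[[i]]
    e <- s + nchar(config$primers$seq[[i]]) - 1L
    rates[s:e] <- config$site_rate
  }
  rates
}

mutate_seq <- function(seqint, p) {
  hit <- which(stats::runif(length(seqint)) < p)
  if (length(hit)) {
    seqint[hit] <- ((seqint[hit] - 1L +
                       sample(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  seqint
}

#' Generate a synthetic reference database
#'
#' Evolves a root sequence down the taxonomy: on every branch each position
#' mutates independently with probability (segment rate x rank multiplier);
#' substitutions only, no indels, so primer coordinates and fragment
#' arithmetic stay exact. The root carries exact binding sites for every
#' configured primer (forward primers as-is, reverse primers as reverse
#' complements), with IUPAC degeneracies resolved once at the root.
#'
#' @param taxonomy Taxonomy from [generate_taxonomy()] (or any taxonomy whose
#'   species names are leaves).
#' @param config The same [sim_config()].
#' @param seed Integer seed; identical config + seed give byte-identical
#'   output.
#' @return A \code{ref_db} with \code{seqs_per_species} records per species.
#' @export
generate_references <- function(taxonomy, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  rates <- position_rates(config)
  with_seed(seed, {
    root <- sample(4L, config$length, replace = TRUE)
    for (i in seq_len(nrow(config$primers))) {
      p <- config$primers[i, ]
      site <- vapply(IUPAC_SETS[chars(p$seq)],
                     function(s) s[[sample.int(length(s), 1)]], character(1))
      if (p$orientation == "reverse") {
        site <- chars(revcomp(paste(site, collapse = "")))
      }
      s <- p$site_start
      root[s:(s + length(site) - 1L)] <- match(site, BASES)
    }
    # evolve depth-first in node-id order (parents precede children)
    seqs <- list(`0` = root)
    ord <- order(rank_depth(taxonomy$rank), taxonomy$id)
    for (row in ord) {
      mult <- config$multipliers[[taxonomy$rank[[row]]]]
      parent_seq <- seqs[[as.character(taxonomy$parent[[row]])]]
      seqs[[as.character(taxonomy$id[[row]])]] <-
        mutate_seq(parent_seq, rates * mult)
    }
    species_rows <- which(taxonomy$rank == "species")
    n <- length(species_rows) * config$seqs_per_species
    ids <- character(n); out <- character(n)
    lin <- matrix(NA_character_, n, 7, dimnames = list(NULL, tax_ranks()))
    k <- 0L
    for (row in species_rows) {
      base <- seqs[[as.character(taxonomy$id[[row]])]]
      l <- node_lineage(taxonomy, taxonomy$id[[row]])
      for (j in seq_len(config$seqs_per_species)) {
        k <- k + 1L
        rec <- if (config$seqs_per_species == 1) base else {
          mutate_seq(base, rates * config$record_multiplier)
        }
        ids[[k]] <- paste0(taxonomy$name[[row]], "_r", j)
        out[[k]] <- int_to_seq(rec)
        lin[k, ] <- l
      }
    }
    ref_db(ids, out, lin)
  })
}

#' Degrade reference annotations
#'
#' Simulates partially annotated reference records: each record is
#' independently selected with probability \code{fraction}, and a selected
#' record's lineage is truncated at a random rank at or above genus (the
#' species name is always lost, possibly more).
#'
#' @param db A \code{ref_db}.
#' @param fraction Probability in \[0, 1\] that a record is degraded.
#' @param seed Integer seed.
#' @return A \code{ref_db} with truncated lineages.
#' @export
degrade_annotations <- function(db, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  with_seed(seed, {
    n <- length(db$id)
    hit <- stats::runif(n) < fraction
    cut <- sample(6L, n, replace = TRUE)  # deepest retained rank index
    lin <- db$lineage
    for (i in which(hit)) {
      if (cut[[i]] < 7L) lin[i, (cut[[i]] + 1L):7L] <- NA_character_
    }
    structure(list(id = db$id, seq = db$seq, lineage = lin), class = "ref_db")
  })
}
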