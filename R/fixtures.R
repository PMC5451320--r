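# Programmatic model generators. Everything the engines and the controller
# need for testing and demonstration is built in code: a lumped
# transcription submodel, a three-compartment minimal cell exercising all
# four formalisms, and a seeded random hybrid model family for fuzzing.

#' Describe an RNA species for the transcription fixture
#'
#' @param id RNA species id (local).
#' @param length Transcript length in nucleotides.
#' @param composition Named counts of A/C/G/U consumed per transcript;
#'   must sum to `length`.
#' @param k_txn Lumped transcription rate constant (per second, under the
#'   combinatorial-count propensity convention).
#' @return An object of class `wc_rna_spec`.
#' @export
rna_spec <- function(id, length, composition, k_txn) {
  composition <- composition[c("A", "C", "G", "U")]
  names(composition) <- c("A", "C", "G", "U")
  if (anyNA(composition) || sum(composition) != length) {
    stop("rna_spec '", id, "': composition must cover A/C/G/U and sum to length",
         call. = FALSE)
  }
  if (k_txn < 0) stop("rna_spec '", id, "': k_txn must be >= 0", call. = FALSE)
  structure(list(id = id, length = length, composition = composition,
                 k_txn = k_txn), class = "wc_rna_spec")
}

.default_rnas <- function() {
  list(rna_spec("RNA1", 4, c(A = 1, C = 1, G = 1, U = 1), 2e-10),
       rna_spec("RNA2", 6, c(A = 2, C = 1, G = 2, U = 1), 4e-14))
}

#' Build the lumped transcription submodel
#'
#' One stochastic reaction per RNA species lumps initiation, elongation and
#' termination: `RNAP + a ATP + c CTP + g GTP + u UTP -> RNAP + RNA_i` at
#' rate constant `k_txn`, with the polymerase acting catalytically. There
#' are no per-base elongation reactions and no explicit DNA-protein
#' binding. Optionally (`rnap_states = TRUE`) a small Markov sub-submodel
#' of polymerase availability is added: the polymerase hops between a free
#' state (the transcription catalyst) and a non-specifically bound state.
#'
#' @param rnas List of [rna_spec()]; defaults keep a 10-second demo in the
#'   hundreds-of-molecules regime.
#' @param n_rnap Initial RNA polymerase copy number (>= 0).
#' @param ntp_counts Named initial counts for ATP/CTP/GTP/UTP.
#' @param compartment Compartment id for all species.
#' @param rnap_states Add the optional polymerase-state variant?
#' @return An SSA [wc_submodel()] with local species ids.
#' @export
make_transcription_submodel <- function(rnas = .default_rnas(), n_rnap = 10,
                                        ntp_counts = c(ATP = 150, CTP = 150,
                                                       GTP = 150, UTP = 150),
                                        compartment = "c",
                                        rnap_states = FALSE) {
  stopifnot(n_rnap >= 0)
  ntp_ids <- c(A = "ATP", C = "CTP", G = "GTP", U = "UTP")
  species <- list(wc_species("RNAP", compartment = compartment,
                             initial_count = n_rnap))
  for (nt in ntp_ids) {
    species[[length(species) + 1L]] <-
      wc_species(nt, compartment = compartment,
                 initial_count = ntp_counts[[nt]] %||% 0)
  }
  reactions <- list()
  for (rna in rnas) {
    species[[length(species) + 1L]] <-
      wc_species(rna$id, compartment = compartment, initial_count = 0)
    comp <- rna$composition[rna$composition > 0]
    reactants <- c(RNAP = 1, stats::setNames(as.numeric(comp), ntp_ids[names(comp)]))
    products <- stats::setNames(c(1, 1), c("RNAP", rna$id))
    reactions[[length(reactions) + 1L]] <-
      wc_reaction(paste0("txn_", rna$id), reactants, products, rna$k_txn)
  }
  if (rnap_states) {
    species[[length(species) + 1L]] <-
      wc_species("RNAP_ns", compartment = compartment, initial_count = 0)
    reactions[[length(reactions) + 1L]] <-
      wc_reaction("rnap_bind_ns", c(RNAP = 1), c(RNAP_ns = 1), 0.1)
    reactions[[length(reactions) + 1L]] <-
      wc_reaction("rnap_release_ns", c(RNAP_ns = 1), c(RNAP = 1), 0.5)
  }
  wc_submodel("transcription", "SSA", species = species, reactions = reactions)
}

#' Build the three-compartment minimal cell model
#'
#' A small whole-cell model with exactly three compartments (extracellular
#' `e`, membrane `m`, cytosol `c`) and four submodels, one per formalism:
#' \itemize{
#'   \item SSA: lumped transcription ([make_transcription_submodel()]);
#'   \item ODE: first-order RNA degradation recycling nucleotides, rate
#'     parameter `k_deg` (retunable by rules);
#'   \item FBA: metabolism importing extracellular glucose through a
#'     membrane transporter, replenishing NTP pools and maximizing a
#'     biomass objective;
#'   \item Boolean: degradation throttling — `k_deg` drops to zero while
#'     both RNA pools are low and is restored once either recovers.
#' }
#' Default kinetic constants keep a 10-second demonstration in the
#' hundreds-of-molecules regime with no request conflicts.
#'
#' @return A list with `model` (composed, validated [wc_model()]),
#'   `manifest` ([wc_manifest()]), and `config` (a [sim_config()] for the
#'   10-second demonstration).
#' @export
make_minimal_cell_model <- function() {
  compartments <- list(
    wc_compartment("e", "extracellular", 1e-12),
    wc_compartment("m", "membrane", 1e-16),
    wc_compartment("c", "cytosol", 1e-15))

  txn <- make_transcription_submodel()
  txn_map <- c(RNAP = "RNAP_c", ATP = "ATP_c", CTP = "CTP_c", GTP = "GTP_c",
               UTP = "UTP_c", RNA1 = "RNA1_c", RNA2 = "RNA2_c")

  deg <- wc_submodel("degradation", "ODE",
    species = list(
      wc_species("RNA1", compartment = "c"),
      wc_species("RNA2", compartment = "c"),
      wc_species("ATP", compartment = "c"), wc_species("CTP", compartment = "c"),
      wc_species("GTP", compartment = "c"), wc_species("UTP", compartment = "c")),
    reactions = list(
      wc_reaction("deg_RNA1", c(RNA1 = 1),
                  c(ATP = 1, CTP = 1, GTP = 1, UTP = 1), "k_deg"),
      wc_reaction("deg_RNA2", c(RNA2 = 1),
                  c(ATP = 2, CTP = 1, GTP = 2, UTP = 1), "k_deg")))
  deg_map <- c(RNA1 = "RNA1_c", RNA2 = "RNA2_c", ATP = "ATP_c", CTP = "CTP_c",
               GTP = "GTP_c", UTP = "UTP_c")

  met <- wc_submodel("metabolism", "FBA",
    species = list(
      wc_species("glc_ext", compartment = "e"),
      wc_species("glc", compartment = "c"),
      wc_species("T", compartment = "m"),
      wc_species("ATP", compartment = "c"), wc_species("CTP", compartment = "c"),
      wc_species("GTP", compartment = "c"), wc_species("UTP", compartment = "c"),
      wc_species("biomass", compartment = "c")),
    reactions = list(
      wc_reaction("uptake", c(glc_ext = 1, T = 1), c(glc = 1, T = 1), 0),
      wc_reaction("synth_A", c(glc = 1), c(ATP = 1), 0),
      wc_reaction("synth_C", c(glc = 1), c(CTP = 1), 0),
      wc_reaction("synth_G", c(glc = 1), c(GTP = 1), 0),
      wc_reaction("synth_U", c(glc = 1), c(UTP = 1), 0),
      wc_reaction("growth", c(ATP = 1, CTP = 1, GTP = 1, UTP = 1),
                  c(biomass = 1), 0)),
    fba = list(
      lower = c(uptake = 0, synth_A = 0, synth_C = 0, synth_G = 0,
                synth_U = 0, growth = 0),
      upper = c(uptake = 40, synth_A = 10, synth_C = 10, synth_G = 10,
                synth_U = 10, growth = 8),
      objective = c(growth = 1, synth_A = 0.01, synth_C = 0.01,
                    synth_G = 0.01, synth_U = 0.01),
      internal = "glc"))
  met_map <- c(glc_ext = "glc_e", glc = "glc_c", T = "T_m", ATP = "ATP_c",
               CTP = "CTP_c", GTP = "GTP_c", UTP = "UTP_c",
               biomass = "biomass_c")

  reg <- wc_submodel("regulation", "BOOLEAN", rules = list(
    boolean_rule("throttle_deg", "RNA1_c < 5 & RNA2_c < 5",
                 list(parameter = "k_deg", value = 0)),
    boolean_rule("restore_deg", "RNA1_c >= 5 | RNA2_c >= 5",
                 list(parameter = "k_deg", value = 0.05))))

  manifest <- wc_manifest(
    submodels = list(txn, deg, met, reg),
    mapping = list(transcription = txn_map, degradation = deg_map,
                   metabolism = met_map),
    compartments = compartments,
    initial_counts = c(RNAP_c = 10, ATP_c = 150, CTP_c = 150, GTP_c = 150,
                       UTP_c = 150, RNA1_c = 0, RNA2_c = 0, glc_e = 600,
                       glc_c = 0, T_m = 5, biomass_c = 0),
    parameters = c(k_deg = 0.05))

  model <- compose_model(manifest)
  list(model = model, manifest = manifest,
       config = sim_config(t_max = 10, dt_init = 0.1, seed = 1L))
}

#' Generate a seeded random hybrid model
#'
#' Fuzz surface for the controller: a valid model with `n_submodels`
#' submodels of alternating SSA/ODE formalism over a shared cytosolic
#' species pool, with first-order conversion reactions at moderate rates.
#' Adjacent submodels share species whenever `n_submodels >= 2`. The same
#' seed always yields the identical model.
#'
#' @param seed Integer generator seed.
#' @param n_species Number of global species (>= 2).
#' @param n_submodels Number of submodels (>= 1).
#' @return A list with `model` and `manifest`, as
#'   [make_minimal_cell_model()].
#' @export
make_random_hybrid_model <- function(seed, n_species = 6, n_submodels = 2) {
  stopifnot(n_species >= 2, n_submodels >= 1)
  comp <- list(wc_compartment("c", "cytosol", 1e-15))
  gids <- sprintf("S%d_c", seq_len(n_species))
  counts <- with_stream(.wc_hash("hybrid-counts", seed), {
    stats::setNames(sample(20:80, n_species, replace = TRUE), gids)
  })

  submodels <- list()
  mapping <- list()
  # contiguous blocks cover every species; each submodel also takes the
  # first species of the next block, so adjacent submodels share species
  blocks <- split(seq_len(n_species),
                  sort(rep_len(seq_len(n_submodels), n_species)))
  for (i in seq_len(n_submodels)) {
    idx <- blocks[[i]]
    if (n_submodels >= 2L) {
      nxt <- blocks[[i %% n_submodels + 1L]][1L]
      idx <- unique(c(idx, nxt))
    }
    local <- sprintf("X%d", seq_along(idx))
    map <- stats::setNames(gids[idx], local)
    n_rxn <- with_stream(.wc_hash("hybrid-nrxn", seed, i), sample(2:3, 1))
    reactions <- list()
    for (j in seq_len(n_rxn)) {
      pick <- with_stream(.wc_hash("hybrid-rxn", seed, i, j), {
        list(from = sample(local, 1),
             to = sample(local, 1),
             k = stats::runif(1, 0.01, 0.1))
      })
      if (pick$from == pick$to) next
      reactions[[length(reactions) + 1L]] <-
        wc_reaction(sprintf("sm%d_r%d", i, j),
                    stats::setNames(1, pick$from), stats::setNames(1, pick$to),
                    pick$k)
    }
    species <- lapply(seq_along(idx), function(k)
      wc_species(local[[k]], compartment = "c"))
    sm_id <- sprintf("sub%02d", i)
    submodels[[i]] <- wc_submodel(sm_id,
                                  if (i %% 2L == 1L) "SSA" else "ODE",
                                  species = species, reactions = reactions)
    mapping[[sm_id]] <- map
  }

  manifest <- wc_manifest(submodels, mapping, comp, initial_counts = counts)
  list(model = compose_model(manifest), manifest = manifest)
}
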