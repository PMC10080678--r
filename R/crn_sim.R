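# Schematic formose-like reaction network in a CSTR: a Breslow-cycle core
# (C1 + C2 aldol chemistry closing through a C4 retro-aldol back to two C2)
# with four gated branches of differing catalyst sensitivity. Kinetics are
# schematic, not fitted: rate constants are chosen so that measured species
# sit at 0.1-10 mM under the unperturbed reference condition and branch
# relaxation times straddle the 30-120 s input timescales.

#' Container for concentration time traces
#'
#' @param times Sampling times in seconds (strictly increasing).
#' @param concentrations Numeric matrix, one row per compound (rownames are
#'   compound ids), one column per time point, in mM; no negative entries.
#' @param modules Optional named character vector of module labels per
#'   compound (`core`, `II`, `III`, `IV`, `V`, `none`).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(times, concentrations, modules = NULL) {
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (!is.matrix(concentrations) || ncol(concentrations) != length(times))
    stop("`concentrations` must be a compound x time matrix", call. = FALSE)
  if (is.null(rownames(concentrations)))
    stop("`concentrations` must have compound ids as rownames", call. = FALSE)
  if (any(concentrations < 0))
    stop("negative concentrations are not allowed", call. = FALSE)
  structure(list(times = times, concentrations = concentrations,
                 modules = modules),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d compounds x %d time points (%g-%g s)\n",
              nrow(x$concentrations), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Write a trace set to CSV (first column `time_s`, one column per compound)
#' @param traces A `trace_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_set <- function(traces, path) {
  df <- data.frame(time_s = traces$times, t(traces$concentrations),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace set from CSV
#' @param path CSV with a `time_s` column and one column per compound.
#' @return A `trace_set`.
#' @export
read_trace_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("trace CSV must have a `time_s` column", call. = FALSE)
  m <- t(as.matrix(df[setdiff(names(df), "time_s")]))
  trace_set(df$time_s, m)
}

#' Catalyst-modulated effective rate constant
#'
#' `k_eff = k * (ca / reference)^sensitivity`: a power-law dependence of a
#' reaction's rate constant on the catalyst (Ca(OH)2) level. Sensitivity 0
#' means catalyst-independent; higher sensitivities transfer faster input
#' fluctuations into the reaction flux.
#'
#' @param k Base rate constant (at the reference catalyst level).
#' @param ca Catalyst concentration (mM, >= 0).
#' @param sensitivity Dimensionless exponent (>= 0).
#' @param catalyst_reference Reference catalyst level (mM, > 0).
#' @return The effective rate constant.
#' @export
effective_rate <- function(k, ca, sensitivity, catalyst_reference) {
  if (any(ca < 0) || catalyst_reference <= 0)
    stop("need ca >= 0 and a positive catalyst reference", call. = FALSE)
  k * (ca / catalyst_reference)^sensitivity
}

reaction <- function(reactants, products, k, sensitivity = 0) {
  list(reactants = reactants, products = products, k = k,
       sensitivity = sensitivity)
}

#' Default rate constants of the schematic formose network
#'
#' Bimolecular constants are per mM per s, unimolecular per s. Values are
#' schematic: chosen so that the measured species reach 0.1-10 mM at the
#' unperturbed steady state and so that core relaxation is faster than the
#' 120 s residence time while branch pools relax on timescales straddling the
#' 30-120 s input fluctuations.
#'
#' @return Named list of rate constants.
#' @export
default_rate_constants <- function() {
  list(
    k_aldol_c2 = 5e-4,    # C1 + GLA -> GLY
    k_iso_gly_f = 1e-3,   # GLY -> DHA
    k_iso_gly_r = 1e-3,   # DHA -> GLY
    k_aldol_c3 = 1e-4,    # C1 + DHA -> ERY
    k_aldol_c4 = 5e-5,    # C1 + GLY -> THR / ERO (aldotetrose route)
    k_dimer_gla = 0,      # 2 GLA -> ERY / THR (optional C2 self-aldol)
    k_retro_gly = 0,      # GLY -> GLA + C1 (optional retro-aldol)
    k_iso_ery_f = 2.5e-3, # ERY -> THR
    k_iso_ery_r = 1.2e-3, # THR -> ERY
    k_iso_ero_f = 2.5e-3, # ERY -> ERO (erythrose-like isomer)
    k_iso_ero_r = 2.5e-3, # ERO -> ERY
    k_iso_tho_f = 2.5e-3, # ERY -> THO (second C4 ketose isomer)
    k_iso_tho_r = 2.5e-3, # THO -> ERY
    k_retro = 6e-3,       # THR -> 2 GLA (Breslow closure)
    k_deg_core = 2.5e-3,  # base-mediated degradation of C4 sugars to tar
    k_gate_II = 5e-5,     # ERY + C1 -> II_C5
    k_gate_III = 3e-3,    # GLY + THR -> III_C7
    k_gate_IV = 3e-3,     # GLY + GLA -> IV_C5
    k_gate_V1 = 3e-4,     # GLA + DHA -> V_C5 (C2-enolate gate)
    k_gate_V2 = 1e-6,     # GLA + ERY -> V_C6a (erythrulose route)
    k_drain_II = 2.5e-2,  # branch-pool drains (condensation to tar)
    k_drain_III = 1e-1,
    k_drain_IV = 1.5e-3,
    k_drain_V = 5e-3
  )
}

#' Default branch catalyst sensitivities
#'
#' Catalyst sensitivities of the gating reactions: branch II is the most
#' catalyst-sensitive gate (it transfers even fast fluctuations), III has a
#' weakly sensitive gate (its response is set by a strongly sensitive drain
#' instead), IV is moderately sensitive with slow pools (transferring only
#' the slower timescales), and V is catalyst-insensitive.
#'
#' @return Named numeric vector with entries `II`, `III`, `IV`, `V`.
#' @export
default_branch_sensitivities <- function() {
  c(II = 3, III = 0.3, IV = 1.5, V = 0)
}

#' Default catalyst sensitivities of the branch-pool drains
#'
#' The retro-cleavage drain of branch III is far more catalyst-sensitive than
#' its gate, so its pools empty when the catalyst level rises and the branch
#' responds with inverted sign; the other branches drain
#' catalyst-independently.
#'
#' @return Named numeric vector with entries `II`, `III`, `IV`, `V`.
#' @export
default_drain_sensitivities <- function() {
  c(II = 0, III = 4, IV = 0, V = 0)
}

#' Default catalyst sensitivities of the core reaction classes
#'
#' The measured C4 sugar pool is degraded to tar by a strongly base-mediated
#' (highly cooperative, exponent 7) channel whose small rate makes the core a
#' slowly relaxing but strongly responding cluster; the Breslow retro-aldol
#' closure is catalyst-promoted (exponent 2.5) while the C2 aldol that
#' consumes glycolaldehyde is only mildly promoted, which gives the
#' unmeasured C2 pool a near-cancelling band-pass response that the
#' catalyst-insensitive branch V inherits. Isomerisations are uniformly and
#' symmetrically promoted, so the composition within the C4 pool is
#' insensitive to the catalyst and its members respond as one block.
#'
#' @return Named numeric vector with entries `aldol_c2`, `iso_gly_f`,
#'   `iso_gly_r`, `aldol_c3`, `aldol_c4`, `dimer`, `retro_gly`, `iso_ery`,
#'   `iso_ero`, `retro`, `deg`.
#' @export
default_core_sensitivities <- function() {
  c(aldol_c2 = 1, iso_gly_f = 1, iso_gly_r = 0.5, aldol_c3 = 0,
    aldol_c4 = 0, dimer = 0, retro_gly = 0, iso_ery = 1, iso_ero = 1,
    retro = 2.5, deg = 7)
}

#' Build the schematic gated formose network
#'
#' The network has a Breslow-cycle core (formaldehyde `C1` + glycolaldehyde
#' `GLA` -> glyceraldehyde `GLY` <-> dihydroxyacetone `DHA`; `C1 + DHA` ->
#' erythrulose `ERY` <-> threose `THR` -> 2 `GLA`, plus an erythrose-like
#' isomer `ERO`) and four branches gated by enolate chemistry of differing
#' catalyst sensitivity: branch II via formaldehyde aldol addition to the C4
#' pool, branch III via C3-enolate + C4 additions paired with a strongly
#' catalyst-sensitive retro-cleavage (off-cycle C4-2,3-enolate route), branch
#' IV via C3-enolate + glycolaldehyde (the xylulose-like route) into
#' slow-relaxing pools, and branch V via catalyst-insensitive C2-enolate
#' additions onto DHA or erythrulose. The measured compounds are DHA and the
#' C4 sugars (the core cluster) plus six species per branch: a gating product
#' whose drain kinetics set the branch's characteristic response, extended by
#' formaldehyde additions into branched/linear C+1 isomers that follow it
#' with fast turnover. The C1/C2/C3 intermediates (formaldehyde,
#' glycolaldehyde, glyceraldehyde) are treated as unmeasured, as are the
#' enolates, which are folded into effective gating rate laws by default
#' (`explicit_enolates = TRUE` adds them as fast explicit species
#' `E32`-`E35`, with the catalyst sensitivity carried by enolate formation).
#'
#' @param branch_sensitivities Named numeric vector (`II`, `III`, `IV`, `V`),
#'   all >= 0; catalyst sensitivities of the gating reactions; see
#'   [default_branch_sensitivities()].
#' @param drain_sensitivities Named numeric vector (`II`, `III`, `IV`, `V`):
#'   catalyst sensitivities of the retro-cleavage drains of each branch pool.
#'   A drain more sensitive than its gate inverts the sign of the branch's
#'   response to catalyst fluctuations.
#' @param core_sensitivities Named numeric vector of catalyst sensitivities
#'   of the core reaction classes (`aldol_c2`, `iso_gly`, `aldol_c3`,
#'   `iso_ery`, `iso_ero`, `retro`); see [default_core_sensitivities()].
#' @param rate_constants Named list overriding [default_rate_constants()].
#' @param catalyst_reference Reference Ca(OH)2 level in mM (default 15).
#' @param explicit_enolates Model enolates as explicit fast species instead
#'   of folding them into the gating rate laws.
#' @return An object of class `network_model`: list with `species` (data
#'   frame: `id`, `carbon`, `module`, `measured`), `reactions`,
#'   `catalyst_reference`, and the sensitivity/rate settings.
#' @export
build_formose_model <- function(branch_sensitivities = default_branch_sensitivities(),
                                drain_sensitivities = default_drain_sensitivities(),
                                core_sensitivities = default_core_sensitivities(),
                                rate_constants = list(),
                                catalyst_reference = 15,
                                explicit_enolates = FALSE) {
  s <- branch_sensitivities
  need_b <- c("II", "III", "IV", "V")
  if (!all(need_b %in% names(s)) ||
      !all(need_b %in% names(drain_sensitivities)))
    stop("branch and drain sensitivities must name II, III, IV and V",
         call. = FALSE)
  sc <- utils::modifyList(as.list(default_core_sensitivities()),
                          as.list(core_sensitivities))
  if (any(s < 0) || any(drain_sensitivities < 0) || any(unlist(sc) < 0))
    stop("catalyst sensitivities must be >= 0", call. = FALSE)
  if (catalyst_reference <= 0)
    stop("catalyst reference must be positive", call. = FALSE)
  k <- utils::modifyList(default_rate_constants(), rate_constants)

  species <- data.frame(
    id = c("C1", "GLA", "GLY", "DHA", "ERY", "THR", "ERO", "THO", "TAR"),
    carbon = c(1, 2, 3, 3, 4, 4, 4, 4, 1),
    module = c("none", "none", "none", "none", rep("core", 4), "none"),
    measured = c(FALSE, FALSE, FALSE, FALSE, rep(TRUE, 4), FALSE),
    stringsAsFactors = FALSE
  )
  reactions <- list()
  add <- function(reactants, products, kk, sens) {
    if (kk <= 0) return(invisible(NULL)) # optional channels off by default
    reactions[[length(reactions) + 1L]] <<- reaction(reactants, products, kk, sens)
  }

  if (explicit_enolates) {
    # enolate formation carries the catalyst sensitivity; additions from the
    # enolate are catalyst-independent. Formation/reversion are fast so the
    # enolates stay quasi-steady.
    k_en <- 0.5   # /s, fast formation at reference catalyst
    k_en_r <- 5   # /s, fast reversion
    species <- rbind(species, data.frame(
      id = c("E32", "E33", "E34", "E35"),
      carbon = c(2, 3, 4, 4),
      module = "none", measured = FALSE
    ))
    add(c(GLA = 1), c(E32 = 1), k_en, s[["V"]])
    add(c(E32 = 1), c(GLA = 1), k_en_r, 0)
    add(c(GLY = 1), c(E33 = 1), k_en, max(s[["III"]], s[["IV"]]))
    add(c(E33 = 1), c(GLY = 1), k_en_r, 0)
    add(c(ERY = 1), c(E34 = 1), k_en, s[["II"]])
    add(c(E34 = 1), c(ERY = 1), k_en_r, 0)
    add(c(THR = 1), c(E35 = 1), k_en, s[["III"]])
    add(c(E35 = 1), c(THR = 1), k_en_r, 0)
  }

  # --- Breslow-cycle core -------------------------------------------------
  add(c(C1 = 1, GLA = 1), c(GLY = 1), k$k_aldol_c2, sc$aldol_c2)
  add(c(GLY = 1), c(DHA = 1), k$k_iso_gly_f, sc$iso_gly_f)
  add(c(DHA = 1), c(GLY = 1), k$k_iso_gly_r, sc$iso_gly_r)
  add(c(C1 = 1, DHA = 1), c(ERY = 1), k$k_aldol_c3, sc$aldol_c3)
  add(c(C1 = 1, GLY = 1), c(THR = 1), k$k_aldol_c4, sc$aldol_c4)
  add(c(C1 = 1, GLY = 1), c(ERO = 1), k$k_aldol_c4 * 0.6, sc$aldol_c4)
  add(c(GLA = 2), c(ERY = 1), k$k_dimer_gla, sc$dimer)
  add(c(GLA = 2), c(THR = 1), k$k_dimer_gla * 0.6, sc$dimer)
  add(c(ERY = 1), c(THR = 1), k$k_iso_ery_f, sc$iso_ery)
  add(c(THR = 1), c(ERY = 1), k$k_iso_ery_r, sc$iso_ery)
  add(c(ERY = 1), c(ERO = 1), k$k_iso_ero_f, sc$iso_ero)
  add(c(ERO = 1), c(ERY = 1), k$k_iso_ero_r, sc$iso_ero)
  add(c(ERY = 1), c(THO = 1), k$k_iso_tho_f, sc$iso_ero)
  add(c(THO = 1), c(ERY = 1), k$k_iso_tho_r, sc$iso_ero)
  add(c(THR = 1), c(GLA = 2), k$k_retro, sc$retro)
  add(c(GLY = 1), c(GLA = 1, C1 = 1), k$k_retro_gly, sc$retro_gly)
  # strongly base-mediated degradation of the C3/C4 sugar pool into
  # unreactive tar (browning); a catalyst-sensitive common drain that the
  # whole core cluster shares
  for (sp in c("ERY", "THR", "ERO", "THO")) {
    cc <- species$carbon[species$id == sp]
    add(stats::setNames(1, sp), c(TAR = cc), k$k_deg_core, sc$deg)
  }

  # --- gated branches -----------------------------------------------------
  # Each branch is a family of parallel pools fed by its gating reaction:
  # with the enolate intermediates folded away, the effective production of
  # the species at chain depth n is gate reactants + n extra formaldehyde in
  # one lumped step carrying the gate's catalyst sensitivity. All pools of a
  # branch share one drain rate and drain sensitivity (condensation into
  # unreactive tar, the browning material of formose chemistry, tracked as a
  # carbon-conserving C1-equivalent waste pool), so the species of a branch
  # respond to the applied dynamics with a common characteristic shape and
  # timescale while their steady levels differ. The lumped rate constants of
  # the deeper additions are normalized at a reference formaldehyde level of
  # 40 mM.
  depth_profile <- c(1, 0.8, 0.7, 0.6, 0.7, 0.6)
  c1_ref <- 40
  branch <- function(prefix, first_carbon, gate_reactants, k_gate, s_gate,
                     k_drain, drain_sens) {
    extra <- c(0, 1, 1, 1, 2, 2)
    carbons <- first_carbon + extra
    suffix <- c("", "a", "b", "c", "a", "b")
    ids <- paste0(prefix, "_C", carbons, suffix)
    for (j in seq_along(ids)) {
      reac <- gate_reactants
      if (extra[j] > 0)
        reac["C1"] <- (if ("C1" %in% names(reac)) reac[["C1"]] else 0) + extra[j]
      add(reac, stats::setNames(1, ids[j]),
          k_gate * depth_profile[j] / c1_ref^extra[j], s_gate)
      add(stats::setNames(1, ids[j]), c(TAR = carbons[j]), k_drain, drain_sens)
    }
    data.frame(id = ids, carbon = carbons, stringsAsFactors = FALSE)
  }

  ds <- drain_sensitivities
  gs <- function(b) if (explicit_enolates) 0 else s[[b]]

  # II: formaldehyde aldol additions onto the C4 pool (C4-1,2-enolate route);
  # the sharply catalyst-sensitive gate and fast pools make this the branch
  # that transfers even fast fluctuations
  sp_II <- branch("II", 5,
                  if (explicit_enolates) c(E34 = 1, C1 = 1) else c(ERY = 1, C1 = 1),
                  if (explicit_enolates) k$k_gate_II * 10 else k$k_gate_II,
                  gs("II"), k$k_drain_II, ds[["II"]])
  sp_II$module <- "II"

  # III: C3-enolate + C4 additions; the weakly sensitive gate is paired with
  # a strongly catalyst-sensitive retro-cleavage (off-cycle C4-2,3-enolate
  # route), so the pools empty when the catalyst level rises and the branch
  # responds with inverted sign
  sp_III <- branch("III", 7,
                   if (explicit_enolates) c(E33 = 1, THR = 1) else c(GLY = 1, THR = 1),
                   if (explicit_enolates) k$k_gate_III * 10 else k$k_gate_III,
                   gs("III"), k$k_drain_III, ds[["III"]])
  sp_III$module <- "III"

  # IV: C3-enolate + glycolaldehyde (xylulose-like C5 route); slow-draining
  # pools give a smooth, lagged response that transfers only the slower
  # input timescales
  sp_IV <- branch("IV", 5,
                  if (explicit_enolates) c(E33 = 1, GLA = 1) else c(GLY = 1, GLA = 1),
                  if (explicit_enolates) k$k_gate_IV * 10 else k$k_gate_IV,
                  gs("IV"), k$k_drain_IV, ds[["IV"]])
  sp_IV$module <- "IV"

  # V: C2-enolate additions onto DHA, erythrulose, or further glycolaldehyde
  # units (C2 self-addition); fully catalyst-insensitive, so it sees the
  # applied dynamics only through the glycolaldehyde pool it feeds from. No
  # formaldehyde enters this branch: all members are lumped multi-additions
  # of C2/C3/C4 units via the C2-enolate.
  v_members <- list(
    V_C5  = c(GLA = 1, DHA = 1),
    V_C6a = c(GLA = 3),
    V_C6b = c(GLA = 3),
    V_C6c = c(GLA = 3),
    V_C7a = c(GLA = 2, DHA = 1),
    V_C7b = c(GLA = 2, DHA = 1)
  )
  v_carbons <- c(5, 6, 6, 6, 7, 7)
  v_k <- k$k_gate_V1 * depth_profile
  gla_ref <- 0.05 # mM, reference glycolaldehyde scale for the lumped additions
  for (j in seq_along(v_members)) {
    extra_order <- sum(v_members[[j]]) - 2L
    if (explicit_enolates) {
      reac <- v_members[[j]]
      reac["GLA"] <- reac[["GLA"]] - 1
      reac <- c(E32 = 1, reac[reac > 0])
      add(reac, stats::setNames(1, names(v_members)[j]),
          v_k[j] * 10 / gla_ref^extra_order, 0)
    } else {
      add(v_members[[j]], stats::setNames(1, names(v_members)[j]),
          v_k[j] / gla_ref^extra_order, gs("V"))
    }
    add(stats::setNames(1, names(v_members)[j]), c(TAR = v_carbons[j]),
        k$k_drain_V, ds[["V"]])
  }
  # the erythrulose route of the C2-enolate gate contributes to one C6 member
  if (explicit_enolates)
    add(c(E32 = 1, ERY = 1), c(V_C6a = 1), k$k_gate_V2 * 10, 0)
  else
    add(c(GLA = 1, ERY = 1), c(V_C6a = 1), k$k_gate_V2, gs("V"))
  sp_V <- data.frame(id = names(v_members), carbon = v_carbons,
                     module = "V", stringsAsFactors = FALSE)

  branch_species <- rbind(sp_II, sp_III, sp_IV, sp_V)
  branch_species$measured <- TRUE
  species <- rbind(species,
                   branch_species[c("id", "carbon", "module", "measured")])
  rownames(species) <- NULL
  if (anyDuplicated(species$id))
    stop("duplicate species ids in model", call. = FALSE)

  model <- structure(
    list(species = species, reactions = reactions,
         catalyst_reference = catalyst_reference,
         branch_sensitivities = s, drain_sensitivities = drain_sensitivities,
         core_sensitivities = unlist(sc),
         rate_constants = k, explicit_enolates = explicit_enolates),
    class = "network_model"
  )
  audit <- carbon_audit(model)
  if (!all(audit$balanced))
    stop("carbon not conserved in reaction(s): ",
         paste(which(!audit$balanced), collapse = ", "), call. = FALSE)
  model
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d species (%d measured), %d reactions\n",
              nrow(x$species), sum(x$species$measured), length(x$reactions)))
  cat("  modules:", paste(sprintf("%s=%d", names(table(x$species$module)),
                                  table(x$species$module)), collapse = " "), "\n")
  cat(sprintf("  catalyst reference %g mM; gate sensitivities %s; drain sensitivities %s\n",
              x$catalyst_reference,
              paste(sprintf("%s=%g", names(x$branch_sensitivities),
                            x$branch_sensitivities), collapse = " "),
              paste(sprintf("%s=%g", names(x$drain_sensitivities),
                            x$drain_sensitivities), collapse = " ")))
  invisible(x)
}

#' Audit carbon conservation of every reaction in a model
#'
#' @param model A `network_model`.
#' @return Data frame with per-reaction carbon counts of reactants and
#'   products and a `balanced` flag.
#' @export
carbon_audit <- function(model) {
  carbon <- stats::setNames(model$species$carbon, model$species$id)
  count <- function(side) sum(carbon[names(side)] * side)
  df <- do.call(rbind, lapply(model$reactions, function(r) {
    data.frame(reactant_C = count(r$reactants), product_C = count(r$products))
  }))
  df$balanced <- df$reactant_C == df$product_C
  df
}

#' Module labels of the measured species
#' @param model A `network_model`.
#' @return Named character vector, compound id -> module label.
#' @export
module_labels <- function(model) {
  m <- model$species[model$species$measured, ]
  stats::setNames(m$module, m$id)
}

# compile the model into index-based structures for fast derivative evaluation
compile_model <- function(model) {
  ids <- c(model$species$id, "ca")
  n_s <- length(ids)
  n_r <- length(model$reactions)
  S <- matrix(0, n_s, n_r, dimnames = list(ids, NULL))
  r_idx <- vector("list", n_r)
  r_pow <- vector("list", n_r)
  for (j in seq_len(n_r)) {
    r <- model$reactions[[j]]
    ri <- match(names(r$reactants), ids)
    pi <- match(names(r$products), ids)
    if (anyNA(ri) || anyNA(pi))
      stop("reaction references unknown species", call. = FALSE)
    S[ri, j] <- S[ri, j] - r$reactants
    # products may include a reactant (net stoichiometry)
    for (q in seq_along(pi)) S[pi[q], j] <- S[pi[q], j] + r$products[q]
    r_idx[[j]] <- ri
    r_pow[[j]] <- as.numeric(r$reactants)
  }
  list(ids = ids, n_s = n_s, S = S, r_idx = r_idx, r_pow = r_pow,
       k = vapply(model$reactions, `[[`, numeric(1), "k"),
       sens = vapply(model$reactions, `[[`, numeric(1), "sensitivity"),
       ref = model$catalyst_reference,
       ca_i = n_s)
}

# mass-action rates at state y (clamped at 0) under catalyst level y[ca]
reaction_rates <- function(cm, y) {
  yc <- pmax(y, 0)
  fac <- (yc[cm$ca_i] / cm$ref)^cm$sens
  r <- cm$k * fac
  for (j in seq_along(r)) {
    if (r[j] != 0) r[j] <- r[j] * prod(yc[cm$r_idx[[j]]]^cm$r_pow[[j]])
  }
  r
}

#' Simulate the network in a CSTR driven by a flow program
#'
#' Integrates the mass balance
#' `dC_i/dt = (C_in,i(t) - C_i) / tau + sum_r nu_ir rate_r(C, ca)` with
#' mass-action kinetics modulated by [effective_rate()]. The catalyst is a
#' non-consumed species with its own mass balance, so the reactor itself
#' low-pass filters the applied input with time constant tau; rate modulation
#' uses this in-reactor catalyst level. Integration proceeds segment by
#' segment between flow-program step boundaries (no smoothing of the step
#' discontinuities).
#'
#' @param model A `network_model`.
#' @param flows A `flow_program` covering `t_span`.
#' @param t_span Length-2 numeric, start and end time in seconds; default the
#'   full program span.
#' @param output_times Times at which to report concentrations; default a
#'   10 s grid over `t_span`.
#' @param y0 Named initial concentrations (mM); species not named start at 0.
#' @param rtol,atol Solver tolerances (deSolve `lsoda`).
#' @param measured_only Keep only measured species (plus the catalyst trace
#'   as compound `ca`) in the output.
#' @return A `trace_set` (attribute `modules` carries module labels);
#'   attribute `clamped` reports how many solver values fell below -1e-12
#'   before clamping.
#' @export
simulate_cstr <- function(model, flows, t_span = NULL, output_times = NULL,
                          y0 = NULL, rtol = 1e-8, atol = 1e-10,
                          measured_only = TRUE) {
  stopifnot(inherits(model, "network_model"), inherits(flows, "flow_program"))
  sched <- flows$schedule
  tau <- flows$reactor$residence_time_s
  prog_end <- sched$time_s[nrow(sched)] + flows$step_interval
  if (is.null(t_span)) t_span <- c(sched$time_s[1], prog_end)
  if (t_span[1] < sched$time_s[1] || t_span[2] > prog_end)
    stop("flow program does not cover the requested time span", call. = FALSE)
  if (is.null(output_times))
    output_times <- seq(t_span[1], t_span[2], by = 10)
  if (any(output_times < t_span[1] | output_times > t_span[2]))
    stop("output times outside t_span", call. = FALSE)

  cm <- compile_model(model)
  y <- stats::setNames(numeric(cm$n_s), cm$ids)
  if (!is.null(y0)) {
    unknown <- setdiff(names(y0), cm$ids)
    if (length(unknown))
      stop("unknown species in y0: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    y[names(y0)] <- y0
  }

  deriv <- function(t, y, parms) {
    r <- reaction_rates(cm, y)
    dy <- as.vector(cm$S %*% r) + (parms$c_in - y) / tau
    list(dy)
  }

  breaks <- sort(unique(c(sched$time_s, t_span)))
  breaks <- breaks[breaks >= t_span[1] & breaks <= t_span[2]]
  if (breaks[length(breaks)] < t_span[2]) breaks <- c(breaks, t_span[2])

  out <- matrix(NA_real_, cm$n_s, length(output_times),
                dimnames = list(cm$ids, NULL))
  emit <- function(tt, yy) {
    hit <- which(abs(output_times - tt) < 1e-9)
    if (length(hit)) out[, hit] <<- yy
  }
  emit(breaks[1], y)
  clamped <- 0L
  for (seg in seq_len(length(breaks) - 1)) {
    t_a <- breaks[seg]; t_b <- breaks[seg + 1]
    if (t_b <= t_a) next
    step <- findInterval(t_a, sched$time_s)
    c_in <- stats::setNames(numeric(cm$n_s), cm$ids)
    if ("C1" %in% cm$ids) c_in["C1"] <- sched$formaldehyde_in_mM[step]
    if ("DHA" %in% cm$ids) c_in["DHA"] <- sched$dha_in_mM[step]
    c_in["ca"] <- sched$cacl2_in_mM[step]
    times <- sort(unique(c(t_a, output_times[output_times > t_a &
                                               output_times <= t_b], t_b)))
    sol <- deSolve::lsoda(y, times, deriv, parms = list(c_in = c_in),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE integration failed in segment [%g, %g] s", t_a, t_b),
           call. = FALSE)
    for (row in 2:nrow(sol)) emit(sol[row, 1], sol[row, -1])
    y <- sol[nrow(sol), -1]
  }
  clamped <- sum(out < -1e-12)
  if (clamped > 0)
    warning(sprintf("%d concentration value(s) below -1e-12 clamped to 0",
                    clamped))
  out <- pmax(out, 0)

  keep <- if (measured_only) c(model$species$id[model$species$measured], "ca")
          else cm$ids
  labels <- module_labels(model)
  ts <- trace_set(output_times, out[keep, , drop = FALSE],
                  modules = labels[intersect(keep, names(labels))])
  attr(ts, "clamped") <- clamped
  ts
}

#' Steady state under a constant input
#'
#' Integrates the model under a constant-inlet flow program until well past
#' the residence time and reports the final state together with the residual
#' norm of the right-hand side (which should be ~0 at steady state).
#'
#' @param model A `network_model`.
#' @param flows A constant `flow_program` (e.g. from a sigma = 0 signal).
#' @param t_end Integration horizon in seconds (default 40 residence times).
#' @return List with `concentrations` (named vector, mM) and `residual`
#'   (max absolute dC/dt in mM/s).
#' @export
steady_state <- function(model, flows, t_end = 40 * flows$reactor$residence_time_s) {
  tau <- flows$reactor$residence_time_s
  sched <- flows$schedule
  sig <- step_signal(rep(sched$cacl2_in_mM[1], 2), t_end / 2)
  fp <- program_flows(sig, flows$inlet, flows$reactor)
  ts <- simulate_cstr(model, fp, output_times = c(0, t_end),
                      measured_only = FALSE)
  y <- ts$concentrations[, ncol(ts$concentrations)]
  cm <- compile_model(model)
  c_in <- stats::setNames(numeric(cm$n_s), cm$ids)
  if ("C1" %in% cm$ids) c_in["C1"] <- fp$schedule$formaldehyde_in_mM[1]
  if ("DHA" %in% cm$ids) c_in["DHA"] <- fp$schedule$dha_in_mM[1]
  c_in["ca"] <- fp$schedule$cacl2_in_mM[1]
  dy <- as.vector(cm$S %*% reaction_rates(cm, y)) + (c_in - y) / tau
  list(concentrations = y, residual = max(abs(dy)))
}

#' Sample the reactor outlet at fixed intervals with measurement noise
#'
#' Interpolates the simulated traces at `start + (0:(n-1)) * interval` and
#' applies multiplicative lognormal noise with the given coefficient of
#' variation per measurement (mean-one noise, so expectations are unbiased).
#'
#' @param traces A `trace_set` from [simulate_cstr()].
#' @param start First sampling time (seconds).
#' @param interval Sampling interval in seconds (e.g. 40.8, or 30.6 for the
#'   multi-timescale program).
#' @param n_samples Number of samples (e.g. 50).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.05); 0 for noiseless sampling.
#' @param seed Integer seed for the noise; identical seeds give identical
#'   samples.
#' @param drop_catalyst Drop the `ca` trace from the output (default TRUE:
#'   the catalyst is not a measured compound).
#' @return A `trace_set` of sampled concentrations.
#' @export
sample_outlet <- function(traces, start, interval, n_samples,
                          noise_cv = 0.05, seed = NULL,
                          drop_catalyst = TRUE) {
  stopifnot(inherits(traces, "trace_set"))
  t_s <- start + (seq_len(n_samples) - 1) * interval
  if (t_s[1] < min(traces$times) || t_s[n_samples] > max(traces$times))
    stop("sampling times extend beyond the simulated span", call. = FALSE)
  m <- traces$concentrations
  if (drop_catalyst && "ca" %in% rownames(m))
    m <- m[setdiff(rownames(m), "ca"), , drop = FALSE]
  sampled <- t(vapply(seq_len(nrow(m)), function(i) {
    stats::approx(traces$times, m[i, ], xout = t_s)$y
  }, numeric(n_samples)))
  rownames(sampled) <- rownames(m)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- with_seed(seed, matrix(
      stats::rlnorm(length(sampled), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow(sampled)))
    sampled <- sampled * noise
  }
  trace_set(t_s, sampled, modules = traces$modules)
}
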