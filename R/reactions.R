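# Internal: canonical species order used throughout the package.
.SPECIES <- c("O2", "NO3", "SO4", "NH4", "Mn2", "Fe2", "HS", "CH4",
              "CO2", "HCO3", "N2", "HPO4",
              "OM1", "OM2", "Mo1", "Mo2", "Foh1", "Foh2",
              "FeS", "FeS2", "Viv", "MnCO3")
.SOLUTES <- .SPECIES[1:12]
.SOLIDS  <- .SPECIES[13:22]

#' Construct a local biogeochemical state
#'
#' A convenience constructor for a single-point state: solute concentrations
#' in umol cm^-3 porewater, solid contents in umol g^-1 dry sediment
#' (organic-matter pools in carbon units).  Unnamed species default to zero.
#'
#' @param ... named concentrations, e.g. `local_state(O2 = 0.1, OM1 = 100)`.
#' @return named numeric vector over all 22 species.
#' @export
local_state <- function(...) {
  s <- stats::setNames(numeric(length(.SPECIES)), .SPECIES)
  v <- c(...)
  if (length(v)) {
    unknown <- setdiff(names(v), .SPECIES)
    if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
    s[names(v)] <- v
  }
  s
}

#' Monod limitation/inhibition factors of the mineralization cascade
#'
#' Organic matter is degraded along the classical terminal-electron-acceptor
#' (TEA) sequence O2 -> NO3- -> Mn-oxides -> Fe-(hydr)oxides -> SO4^2- ->
#' methanogenesis.  Each pathway i carries a Monod limitation in its own TEA
#' and a multiplicative inhibition by every energetically superior TEA, using
#' the same half-saturation constant K for limitation and inhibition.  The
#' oxide limitations use the reactive pools (Mo1, Foh1; umol g^-1) -- the
#' pools the pathways actually consume; solute TEAs are in umol cm^-3.
#' Methanogenesis carries only the five inhibition terms, so it approaches 1
#' when all TEAs are exhausted.
#'
#' @param state named species vector (see [local_state()]) or an
#'   nodes-by-species matrix.
#' @param p parameter set.
#' @return matrix with columns `oxic`, `denitrification`, `Mn_reduction`,
#'   `Fe_reduction`, `SO4_reduction`, `methanogenesis`, all in \[0, 1\].
#' @examples
#' f <- limitation_factors(local_state(O2 = 0.1), default_parameters())
#' f[, "oxic"]  # ~0.99
#' @export
limitation_factors <- function(state, p) {
  C <- if (is.matrix(state)) state else
    matrix(state, nrow = 1, dimnames = list(NULL, names(state)))
  tea <- cbind(C[, "O2"], C[, "NO3"], C[, "Mo1"], C[, "Foh1"], C[, "SO4"])
  K <- c(p$K_O2, p$K_NO3, p$K_MnO2, p$K_FeOOH, p$K_SO4)
  # Monod in the own TEA; |x| in the denominator continues the law smoothly
  # (and restoringly) through the tiny negative excursions of stiff solvers
  lim <- sweep(tea, 2, K, function(x, k) x / (abs(x) + k))
  inh <- 1 - lim                                        # K/(TEA+K)
  f <- matrix(0, nrow(C), 6L,
              dimnames = list(NULL, c("oxic", "denitrification", "Mn_reduction",
                                      "Fe_reduction", "SO4_reduction",
                                      "methanogenesis")))
  cum <- rep(1, nrow(C))
  for (i in 1:5) {
    f[, i] <- lim[, i] * cum
    cum <- cum * inh[, i]
  }
  f[, 6] <- cum
  f
}

#' Primary mineralization rates of the reactive organic-matter pool
#'
#' First-order decay of the reactive pool OM1 (the non-reactive pool OM2 is
#' inert), partitioned over the six pathways by [limitation_factors()].  For
#' every carbon mineralized, nitrogen, phosphorus and sulfur are liberated in
#' the elemental ratio of the organic matter (cy/cx as NH4+, cz/cx as
#' HPO4^2-, cs/cx as S(-II)); methanogenesis splits carbon 1:1 into CH4 and
#' CO2; denitrification routes nitrate either to N2 (lost to the water
#' column) or, for the DNRA branch, to NH4+.
#'
#' @param state named species vector or nodes-by-species matrix.
#' @param p parameter set.
#' @return list with `pathways` (C-mineralization per pathway,
#'   umol C g^-1 yr^-1), `total_C`, and released `NH4`, `HPO4`, `HS`, `CH4`,
#'   `CO2` (same units).
#' @examples
#' r <- primary_mineralization(local_state(OM1 = 100), default_parameters())
#' r$pathways[, "methanogenesis"]  # 5.28: k_deg_CH4 * 100
#' @export
primary_mineralization <- function(state, p) {
  C <- if (is.matrix(state)) state else
    matrix(state, nrow = 1, dimnames = list(NULL, names(state)))
  if (any(C[, "OM1"] < 0)) stop("OM1 must be non-negative")
  f <- limitation_factors(C, p)
  k <- c(p$k_deg_O2, p$k_deg_NO3, p$k_deg_MnO2, p$k_deg_FeOOH,
         p$k_deg_SO4, p$k_deg_CH4)
  pw <- sweep(f, 2, k, "*") * C[, "OM1"]
  colnames(pw) <- colnames(f)
  totC <- rowSums(pw)
  dnra_C <- p$f_dnra * pw[, "denitrification"]
  list(pathways = pw,
       total_C = totC,
       NH4  = (p$cy / p$cx) * totC + 0.5 * dnra_C,
       HPO4 = (p$cz / p$cx) * totC,
       HS   = (p$cs / p$cx) * totC,
       CH4  = 0.5 * pw[, "methanogenesis"],
       CO2  = totC - 0.5 * pw[, "methanogenesis"])
}

# Internal: reaction context -------------------------------------------------
#
# All reaction bookkeeping lives in a single stoichiometry matrix on a common
# porewater-volume basis (umol cm^-3 porewater).  Solid contents (umol g^-1)
# are converted with the mass-to-porewater factor m/phi = rho_b*(1-phi)/phi.
# Each reaction row gives the species increments per unit reaction extent.

.reaction_names <- c(
  "min_O2", "min_NO3", "min_DNRA", "min_MnO2", "min_FeOOH", "min_SO4", "min_CH4",
  "nhox", "mox", "fox", "sox", "chox",
  "nhmo", "nhmx", "nhfo", "nhfx",
  "fmo", "fmx", "smo", "smx", "sfo", "sfx",
  "chso", "moN",
  "viv_pre", "viv_dis", "viv_sulf", "FeS_pre", "FeS_dis", "pyr_pre", "MnCO3_pre")

#' Stoichiometry matrix of the reaction network
#'
#' One row per reaction, one column per species; entries are the species
#' increments per unit reaction extent on a common porewater-volume basis
#' (umol cm^-3 porewater).  Primary mineralization extents are per mol C,
#' secondary redox extents per mol of reduced species oxidized, mineral
#' extents per mol formula unit.  The matrix is the single source of truth
#' for source-term assembly and is exportable for audit with
#' [write_stoichiometry()].
#'
#' @param p parameter set (supplies the elemental ratio and DNRA branch).
#' @return numeric matrix (reactions x species).
#' @export
stoichiometry_matrix <- function(p = default_parameters()) {
  S <- matrix(0, length(.reaction_names), length(.SPECIES),
              dimnames = list(.reaction_names, .SPECIES))
  ny <- p$cy / p$cx; nz <- p$cz / p$cx; ns <- p$cs / p$cx
  rel <- c(NH4 = ny, HPO4 = nz, HS = ns, OM1 = -1)   # common to all pathways
  set <- function(r, ...) {
    v <- c(...)
    # accumulate entry by entry: species may appear twice in one reaction
    # (e.g. the DNRA row adds NH4 from both the elemental release and the
    # reduced nitrate)
    for (k in seq_along(v))
      S[r, names(v)[k]] <<- S[r, names(v)[k]] + v[[k]]
  }
  set("min_O2",    rel, c(O2 = -1, CO2 = 1))
  set("min_NO3",   rel, c(NO3 = -0.8, N2 = 0.4, CO2 = 1))
  set("min_DNRA",  rel, c(NO3 = -0.5, NH4 = 0.5, CO2 = 1))
  set("min_MnO2",  rel, c(Mo1 = -2, Mn2 = 2, CO2 = 1))
  set("min_FeOOH", rel, c(Foh1 = -4, Fe2 = 4, CO2 = 1))
  set("min_SO4",   rel, c(SO4 = -0.5, HS = 0.5, CO2 = 1))
  set("min_CH4",   rel, c(CH4 = 0.5, CO2 = 0.5))
  set("nhox", c(NH4 = -1, O2 = -2, NO3 = 1))
  set("mox",  c(Mn2 = -1, O2 = -0.5, Mo1 = 1))
  set("fox",  c(Fe2 = -1, O2 = -0.25, Foh1 = 1))
  set("sox",  c(HS = -1, O2 = -2, SO4 = 1))
  set("chox", c(CH4 = -1, O2 = -2, CO2 = 1))
  set("nhmo", c(NH4 = -1, Mo1 = -1.5, Mn2 = 1.5, N2 = 0.5))
  set("nhmx", c(NH4 = -1, Mo2 = -1.5, Mn2 = 1.5, N2 = 0.5))
  set("nhfo", c(NH4 = -1, Foh1 = -3, Fe2 = 3, N2 = 0.5))
  set("nhfx", c(NH4 = -1, Foh2 = -3, Fe2 = 3, N2 = 0.5))
  set("fmo",  c(Fe2 = -1, Mo1 = -0.5, Mn2 = 0.5, Foh1 = 1))
  set("fmx",  c(Fe2 = -1, Mo2 = -0.5, Mn2 = 0.5, Foh1 = 1))
  set("smo",  c(HS = -1, Mo1 = -4, Mn2 = 4, SO4 = 1))
  set("smx",  c(HS = -1, Mo2 = -4, Mn2 = 4, SO4 = 1))
  set("sfo",  c(HS = -1, Foh1 = -8, Fe2 = 8, SO4 = 1))
  set("sfx",  c(HS = -1, Foh2 = -8, Fe2 = 8, SO4 = 1))
  set("chso", c(CH4 = -1, SO4 = -1, HS = 1, CO2 = 1))
  set("moN",  c(Mn2 = -1, NO3 = -0.4, Mo1 = 1, N2 = 0.2))
  set("viv_pre",   c(Fe2 = -3, HPO4 = -2, Viv = 1))
  set("viv_dis",   c(Viv = -1, Fe2 = 3, HPO4 = 2))
  set("viv_sulf",  c(Viv = -1, HS = -3, FeS = 3, HPO4 = 2))
  set("FeS_pre",   c(Fe2 = -1, HS = -1, FeS = 1))
  set("FeS_dis",   c(FeS = -1, Fe2 = 1, HS = 1))
  set("pyr_pre",   c(FeS = -1, HS = -1, FeS2 = 1))
  set("MnCO3_pre", c(Mn2 = -1, HCO3 = -1, MnCO3 = 1))
  S
}

#' Element composition matrix
#'
#' Moles of each tracked element per mole of species, with organic-matter
#' pools carrying the elemental ratio per carbon.  Used by the elemental
#' conservation audits: the stoichiometry matrix must annihilate this matrix
#' for every closed element (N2 is the open nitrogen channel and counts 2 N).
#'
#' @param p parameter set.
#' @return matrix species x elements (C, N, P, S, Fe, Mn).
#' @export
element_composition <- function(p = default_parameters()) {
  E <- matrix(0, length(.SPECIES), 6L,
              dimnames = list(.SPECIES, c("C", "N", "P", "S", "Fe", "Mn")))
  E[c("CH4", "CO2", "HCO3", "MnCO3"), "C"] <- 1
  E[c("OM1", "OM2"), "C"] <- 1
  E[c("OM1", "OM2"), "N"] <- p$cy / p$cx
  E[c("OM1", "OM2"), "P"] <- p$cz / p$cx
  E[c("OM1", "OM2"), "S"] <- p$cs / p$cx
  E[c("NO3", "NH4"), "N"] <- 1
  E["N2", "N"] <- 2
  E[c("HPO4"), "P"] <- 1
  E["Viv", "P"] <- 2
  E[c("SO4", "HS"), "S"] <- 1
  E["FeS", "S"] <- 1; E["FeS2", "S"] <- 2
  E[c("Fe2", "Foh1", "Foh2", "FeS"), "Fe"] <- 1
  E["FeS2", "Fe"] <- 1; E["Viv", "Fe"] <- 3
  E[c("Mn2", "Mo1", "Mo2", "MnCO3"), "Mn"] <- 1
  E
}

# Internal: C1-smooth stand-in for max(x, 0), exactly zero below the
# threshold; identical to the compiled kernel (src/rhs.cpp).  Keeping the
# rate laws once differentiable prevents step-size chatter in the stiff
# integrator at the saturation thresholds.
.hinge <- function(x, eps) {
  ifelse(x <= 0, 0, ifelse(x >= eps, x - 0.5 * eps, 0.5 * x * x / eps))
}

# Internal: precomputed context for fast source-term evaluation.
.reaction_context <- function(p) {
  S <- stoichiometry_matrix(p)
  m_phi <- p$rho_b * (1 - p$porosity) / p$porosity  # g solid per cm^3 porewater
  solid <- .SPECIES %in% .SOLIDS
  # Rate limitation at vanishing reactant concentrations: every consumption
  # term is already proportional to (or Monod in) each consumed species, so
  # rates go to zero with the reactant exactly as the rate-limiting constant
  # L intends; at geochemically meaningful concentrations the literal
  # multiplicative factor C/(C+L) with L = 1e-8 equals one to within 1e-8,
  # while its switch at the 1e-8 scale destroys stiff step-size control.
  # The guard machinery is therefore kept but empty by default.
  guards <- rep(list(integer(0)), nrow(S))
  list(S = S, m_phi = m_phi, solid = solid, guards = guards,
       kdeg = c(p$k_deg_O2, p$k_deg_NO3, p$k_deg_MnO2, p$k_deg_FeOOH,
                p$k_deg_SO4, p$k_deg_CH4))
}

# Internal: all reaction extents (nodes x reactions) on the porewater-volume
# basis.  `Cpw` must already be on that basis (solids multiplied by m/phi);
# `Csolid` carries the native umol g^-1 solid contents needed by the
# oxide-pool limitation terms and the mineral rate laws.
# Rate laws are evaluated on the raw state (matching src/rhs.cpp): every
# consumption is linear or Monod in the consumed species, hence smoothly
# restoring around zero.
.reaction_extents <- function(Cpw, Csolid, p, ctx) {
  n <- nrow(Cpw)
  R <- matrix(0, n, length(.reaction_names),
              dimnames = list(NULL, .reaction_names))
  st <- cbind(Cpw[, 1:12, drop = FALSE], Csolid)
  colnames(st) <- .SPECIES
  f <- limitation_factors(st, p)
  OM1pw <- Cpw[, "OM1"]
  base <- sweep(f, 2, ctx$kdeg, "*") * OM1pw
  R[, "min_O2"]    <- base[, 1]
  R[, "min_NO3"]   <- (1 - p$f_dnra) * base[, 2]
  R[, "min_DNRA"]  <- p$f_dnra * base[, 2]
  R[, "min_MnO2"]  <- base[, 3]
  R[, "min_FeOOH"] <- base[, 4]
  R[, "min_SO4"]   <- base[, 5]
  R[, "min_CH4"]   <- base[, 6]
  O2 <- Cpw[, "O2"]
  R[, "nhox"] <- p$k_nhox * Cpw[, "NH4"] * O2
  R[, "mox"]  <- p$k_mox  * Cpw[, "Mn2"] * O2
  R[, "fox"]  <- p$k_fox  * Cpw[, "Fe2"] * O2
  R[, "sox"]  <- p$k_sox  * Cpw[, "HS"]  * O2
  R[, "chox"] <- p$k_chox * Cpw[, "CH4"] * O2
  R[, "nhmo"] <- p$k_nhmo * Cpw[, "NH4"] * Cpw[, "Mo1"]
  R[, "nhmx"] <- p$k_nhmx * Cpw[, "NH4"] * Cpw[, "Mo2"]
  R[, "nhfo"] <- p$k_nhfo * Cpw[, "NH4"] * Cpw[, "Foh1"]
  R[, "nhfx"] <- p$k_nhfx * Cpw[, "NH4"] * Cpw[, "Foh2"]
  R[, "fmo"]  <- p$k_fmo  * Cpw[, "Fe2"] * Cpw[, "Mo1"]
  R[, "fmx"]  <- p$k_fmx  * Cpw[, "Fe2"] * Cpw[, "Mo2"]
  R[, "smo"]  <- p$k_smo  * Cpw[, "HS"]  * Cpw[, "Mo1"]
  R[, "smx"]  <- p$k_smx  * Cpw[, "HS"]  * Cpw[, "Mo2"]
  R[, "sfo"]  <- p$k_sfo  * Cpw[, "HS"]  * Cpw[, "Foh1"]
  R[, "sfx"]  <- p$k_sfx  * Cpw[, "HS"]  * Cpw[, "Foh2"]
  R[, "chso"] <- p$k_chso * Cpw[, "CH4"] * Cpw[, "SO4"]
  R[, "moN"]  <- p$k_moN  * Cpw[, "Mn2"] * Cpw[, "NO3"]
  # mineral saturation states
  omega_viv <- (.hinge(Cpw[, "Fe2"], 1e-6) * 1e-3)^3 *
               (.hinge(Cpw[, "HPO4"], 1e-6) * 1e-3)^2 / p$k_EqViv
  Hm <- p$H_plus * 1e3   # proton activity on the umol cm^-3 scale
  omega_fes <- Cpw[, "Fe2"] * Cpw[, "HS"] / Hm / p$k_EqFeS
  co3 <- p$k_EqHCO3CO3 * Cpw[, "HCO3"] / Hm
  omega_mnc <- Cpw[, "Mn2"] * co3 / p$k_EqMnCO3
  m_phi <- ctx$m_phi
  R[, "viv_pre"]   <- p$k_vivpre * .hinge(omega_viv - 1, 0.1) * m_phi
  R[, "viv_dis"]   <- p$k_vivdis * Csolid[, "Viv"] * .hinge(1 - omega_viv, 0.1) * m_phi
  R[, "viv_sulf"]  <- p$k_sviv * Csolid[, "Viv"] * Cpw[, "HS"] * m_phi
  R[, "FeS_pre"]   <- p$k_FeSpre * .hinge(omega_fes - 1, 0.1) * m_phi
  R[, "FeS_dis"]   <- p$k_FeSdis * Csolid[, "FeS"] * .hinge(1 - omega_fes, 0.1) * m_phi
  R[, "pyr_pre"]   <- p$k_pyrpre * Csolid[, "FeS"] * Cpw[, "HS"] * m_phi
  R[, "MnCO3_pre"] <- p$k_MnCO3pre * .hinge(omega_mnc - 1, 0.1) * m_phi
  # L-guard: every consumption term is damped by C/(C+L) in each consumed
  # species, which drives rates smoothly to zero as a reactant is exhausted.
  L <- p$L
  Cg <- Cpw
  for (r in seq_along(ctx$guards)) {
    gi <- ctx$guards[[r]]
    if (!length(gi)) next
    g <- Cg[, gi[1]] / (Cg[, gi[1]] + L)
    for (k in gi[-1]) g <- g * (Cg[, k] / (Cg[, k] + L))
    R[, r] <- R[, r] * g
  }
  R
}

#' Net volumetric source terms
#'
#' Assembles every reaction in the network into one net production rate per
#' species.  Rates are evaluated on a common porewater-volume basis and the
#' solid-species tendencies converted back to their native umol g^-1 yr^-1
#' with phi/(rho_b (1-phi)).
#'
#' @param state named species vector or nodes-by-species matrix (native
#'   units: solutes umol cm^-3, solids umol g^-1).
#' @param p parameter set.
#' @return matrix of tendencies (nodes x species) in native units per year;
#'   a single-row matrix for a vector state.
#' @examples
#' src <- net_source_terms(local_state(OM1 = 100, O2 = 0.2), default_parameters())
#' src[, "O2"] < 0   # oxic mineralization consumes O2
#' @export
net_source_terms <- function(state, p) {
  C <- if (is.matrix(state)) state else
    matrix(state, nrow = 1, dimnames = list(NULL, names(state)))
  C <- C[, .SPECIES, drop = FALSE]
  ctx <- .reaction_context(p)
  Csolid <- C[, .SOLIDS, drop = FALSE]
  Cpw <- C
  Cpw[, .SOLIDS] <- Cpw[, .SOLIDS] * ctx$m_phi
  R <- .reaction_extents(Cpw, Csolid, p, ctx)
  src <- R %*% ctx$S
  src[, .SOLIDS] <- src[, .SOLIDS] / ctx$m_phi
  src
}

#' Export the stoichiometry table for audit
#'
#' Writes the reaction-by-species stoichiometry matrix as a tab-separated
#' table.
#'
#' @param path output file path.
#' @param p parameter set.
#' @return the path, invisibly.
#' @export
write_stoichiometry <- function(path, p = default_parameters()) {
  S <- stoichiometry_matrix(p)
  utils::write.table(data.frame(reaction = rownames(S), S,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
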