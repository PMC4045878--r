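# Pathway stoichiometry and flux algebra for the Pdu pathway:
# glycerol --v1--> 3HPA --v2--> 1,3PDO (NADH -> NAD+)
#                       --v3--> 3HP    (NAD+ -> NADH, + ATP)
#                       --v4--> net extracellular 3HPA accumulation
# v3 lumps the three oxidative steps (PduP/PduL/PduW); CoA and the acyl
# intermediates cycle internally and net to zero.

#' Metabolites of the Pdu pathway network
#'
#' Standard molar masses (g/mol, 2 decimals) and roles for every species
#' appearing in the pathway, including cofactors and the carbohydrazide
#' scavenger used for in situ 3HPA complexation.
#'
#' @return A data.frame with columns `id`, `name`, `molar_mass` (g/mol) and
#'   `role` (substrate, intermediate, product, cofactor, scavenger, complex).
#' @export
pdu_metabolites <- function() {
  data.frame(
    id = c("glycerol", "hpa", "pdo", "hp",
           "hp_coa", "hp_phosphate",
           "nadh", "nad", "atp", "adp", "coa",
           "carbohydrazide", "hpa_complex"),
    name = c("glycerol", "3-hydroxypropionaldehyde", "1,3-propanediol",
             "3-hydroxypropionic acid", "3-hydroxypropionyl-CoA",
             "3-hydroxypropionyl phosphate", "NADH", "NAD+", "ATP", "ADP",
             "coenzyme A", "carbohydrazide", "3HPA-carbohydrazide complex"),
    molar_mass = c(92.09, 74.08, 76.09, 90.08,
                   839.59, 170.06,
                   665.44, 663.43, 507.18, 427.20, 767.53,
                   90.09, 146.15),
    role = c("substrate", "intermediate", "product", "product",
             "intermediate", "intermediate",
             "cofactor", "cofactor", "cofactor", "cofactor", "cofactor",
             "scavenger", "complex"),
    stringsAsFactors = FALSE
  )
}

#' Build the Pdu pathway stoichiometric network
#'
#' Constructs the fixed four-flux network of glycerol biotransformation by
#' resting \emph{L. reuteri} cells: `v1` glycerol dehydration to 3HPA by the
#' B12-dependent glycerol/diol dehydratase (PduCDE); `v2` 3HPA reduction to
#' 1,3PDO by the 1,3-propanediol oxidoreductase (PduQ), consuming NADH;
#' `v3` the lumped oxidative branch (PduP/PduL/PduW) producing 3HP,
#' regenerating NADH and yielding one ATP per 3HP; and `v4`, a bookkeeping
#' pseudo-flux for net extracellular 3HPA accumulation (defined as
#' `v1 - v2 - v3`). The acyl intermediates (3HP-CoA, 3HP-phosphate) and CoA
#' cycle inside the lumped `v3` and carry zero net coefficients; they are
#' retained in the metabolite table for documentation.
#'
#' @param file Optional path to a YAML/JSON network definition with elements
#'   `metabolites` (list of `id`, `molar_mass`, `role`) and `stoichiometry`
#'   (map reaction -> map metabolite -> signed coefficient). Defaults to the
#'   built-in network shipped in `inst/extdata/pdu_network.yaml`.
#' @return An object of class `pdu_network`: a list with `metabolites`
#'   (data.frame) and `stoich` (integer matrix, metabolites x reactions
#'   `v1..v4`).
#' @examples
#' net <- build_pdu_network()
#' net$stoich["nadh", ]   # c(0, -1, 1, 0)
#' @export
build_pdu_network <- function(file = NULL) {
  if (is.null(file)) {
    met <- pdu_metabolites()
    rxn <- c("v1", "v2", "v3", "v4")
    S <- matrix(0L, nrow = nrow(met), ncol = length(rxn),
                dimnames = list(met$id, rxn))
    S["glycerol", "v1"] <- -1L
    S["hpa", ] <- c(1L, -1L, -1L, 1L)
    S["pdo", "v2"] <- 1L
    S["hp", "v3"] <- 1L
    S["nadh", ] <- c(0L, -1L, 1L, 0L)
    S["nad", ] <- c(0L, 1L, -1L, 0L)
    S["atp", "v3"] <- 1L
    S["adp", "v3"] <- -1L
    # v4 is an accumulation column: +1 on 3HPA only, overwritten last so the
    # bookkeeping definition holds even if the hpa row above changes.
    S[, "v4"] <- 0L
    S["hpa", "v4"] <- 1L
  } else {
    def <- read_structured_config(file)
    met <- do.call(rbind, lapply(def$metabolites, function(m) {
      data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
                 molar_mass = as.numeric(m$molar_mass), role = m$role,
                 stringsAsFactors = FALSE)
    }))
    rxn <- names(def$stoichiometry)
    S <- matrix(0L, nrow = nrow(met), ncol = length(rxn),
                dimnames = list(met$id, rxn))
    for (r in rxn) {
      for (sp in names(def$stoichiometry[[r]])) {
        if (!sp %in% met$id)
          stop("stoichiometry references unknown metabolite '", sp, "'")
        S[sp, r] <- as.integer(def$stoichiometry[[r]][[sp]])
      }
    }
  }
  if (anyDuplicated(met$id))
    stop("metabolite ids must be unique")
  if (any(!is.finite(met$molar_mass)) || any(met$molar_mass <= 0))
    stop("all molar masses must be positive")
  structure(list(metabolites = met, stoich = S), class = "pdu_network")
}

#' @export
print.pdu_network <- function(x, ...) {
  cat("Pdu pathway network:", nrow(x$metabolites), "metabolites,",
      ncol(x$stoich), "net fluxes\n")
  active <- x$stoich[rowSums(x$stoich != 0) > 0, , drop = FALSE]
  print(active)
  invisible(x)
}

#' Look up the molar mass of a network species
#'
#' @param species Metabolite id (e.g. `"glycerol"`, `"hpa"`).
#' @param network A `pdu_network`; defaults to the built-in one.
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(species, network = build_pdu_network()) {
  i <- match(species, network$metabolites$id)
  if (anyNA(i))
    stop("unknown species id: '", paste(species[is.na(i)], collapse = "', '"),
         "'")
  network$metabolites$molar_mass[i]
}

#' Convert a mass-specific rate to a molar-specific rate
#'
#' Bridges the mg/g_CDW.h units of reported specific rates and the
#' mmol/g_CDW.h units used in the node and redox balances. Sign is
#' preserved (consumption rates stay negative).
#'
#' @param q_mass Specific rate in mg/g_CDW.h.
#' @param species Metabolite id naming the species the rate is expressed in.
#' @param network A `pdu_network`.
#' @return Specific rate in mmol/g_CDW.h.
#' @examples
#' mass_to_molar(-266.2, "glycerol")  # -2.891
#' @export
mass_to_molar <- function(q_mass, species, network = build_pdu_network()) {
  q_mass / molar_mass(species, network)
}

#' Convert a molar-specific rate to a mass-specific rate
#'
#' Inverse of [mass_to_molar()].
#'
#' @inheritParams mass_to_molar
#' @param q_molar Specific rate in mmol/g_CDW.h.
#' @return Specific rate in mg/g_CDW.h.
#' @export
molar_to_mass <- function(q_molar, species, network = build_pdu_network()) {
  q_molar * molar_mass(species, network)
}

# Species each flux is expressed in (Table-1 column mapping).
flux_species <- c(v1 = "glycerol", v2 = "pdo", v3 = "hp", v4 = "hpa")

#' Construct a specific flux vector
#'
#' Holds the four net specific fluxes of the pathway in both molar
#' (mmol/g_CDW.h) and mass (mg/g_CDW.h) units. Each flux is expressed in
#' the species conventionally reported for it: `v1` in glycerol, `v2` in
#' 1,3PDO, `v3` in 3HP and `v4` in 3HPA. Consumption is stored negative
#' and production positive, so `v1` is normally negative.
#'
#' @param v1,v2,v3,v4 The four specific fluxes.
#' @param units `"mmol"` (mmol/g_CDW.h, default) or `"mg"` (mg/g_CDW.h)
#'   for the values supplied; both forms are stored.
#' @param network A `pdu_network` providing molar masses.
#' @return An object of class `flux_vector` with elements `molar` and
#'   `mass`, each a named numeric vector `v1..v4`.
#' @examples
#' f <- flux_vector(v1 = -2.891, v2 = 1.25, v3 = 1.25, v4 = 0.391)
#' f$mass["v3"]   # ~112.6 mg/g_CDW.h
#' @export
flux_vector <- function(v1, v2, v3, v4, units = c("mmol", "mg"),
                        network = build_pdu_network()) {
  units <- match.arg(units)
  v <- c(v1 = v1, v2 = v2, v3 = v3, v4 = v4)
  if (anyNA(v) || any(!is.finite(v)))
    stop("all four fluxes must be present and finite")
  mm <- molar_mass(unname(flux_species), network)
  if (units == "mmol") {
    molar <- v
    mass <- v * mm
  } else {
    mass <- v
    molar <- v / mm
  }
  names(mass) <- names(molar) <- names(flux_species)
  structure(list(molar = molar, mass = mass), class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, digits = 4, ...) {
  cat("Specific fluxes (consumption negative):\n")
  print(round(rbind(`mmol/g_CDW.h` = x$molar, `mg/g_CDW.h` = x$mass),
              digits))
  invisible(x)
}

as_flux_vector <- function(f) {
  if (!inherits(f, "flux_vector"))
    stop("expected a 'flux_vector' object")
  f
}

#' Residual of the molar node balance around 3HPA
#'
#' The 3HPA node is rigid: all glycerol dehydrated by GDH must leave as
#' 1,3PDO, 3HP or net 3HPA accumulation. The residual `|v1| - v2 - v3 - v4`
#' (mmol/g_CDW.h) is zero at perfect closure; consumption magnitude is used
#' because `v1` is stored negative.
#'
#' @param f A `flux_vector`.
#' @return Residual in mmol/g_CDW.h.
#' @export
node_balance_residual <- function(f) {
  f <- as_flux_vector(f)
  v <- f$molar
  abs(v[["v1"]]) - v[["v2"]] - v[["v3"]] - v[["v4"]]
}

#' Residual of the redox (NADH) balance between the two branches
#'
#' The reductive branch consumes one NADH per 1,3PDO and the oxidative
#' branch regenerates one NADH per 3HP, so zero net cofactor drift requires
#' `v3 = v2`. Returns `v3 - v2` in mmol/g_CDW.h.
#'
#' @param f A `flux_vector`.
#' @return Residual in mmol/g_CDW.h.
#' @export
redox_residual <- function(f) {
  f <- as_flux_vector(f)
  f$molar[["v3"]] - f$molar[["v2"]]
}

#' Flux split ratio around the 3HPA node
#'
#' Mol% partition of the 3HPA flux leaving the node between the oxidative
#' (3HP) and reductive (1,3PDO) branches. The two components always sum to
#' 100.
#'
#' @param f A `flux_vector` with `v2 + v3 > 0` (molar).
#' @return Named numeric `c(to_3HP = ..., to_PDO = ...)` in mol%.
#' @export
split_ratio <- function(f) {
  f <- as_flux_vector(f)
  v2 <- f$molar[["v2"]]; v3 <- f$molar[["v3"]]
  tot <- v2 + v3
  if (tot <= 0)
    stop("split ratio undefined: v2 + v3 must be positive")
  c(to_3HP = 100 * v3 / tot, to_PDO = 100 * v2 / tot)
}

#' Infer the branch fluxes from uptake and accumulation by node + redox balance
#'
#' Given the glycerol uptake flux `v1` and the net 3HPA accumulation flux
#' `v4`, the rigid node balance (`|v1| = v2 + v3 + v4`) combined with the
#' redox constraint (`v2 = v3`, zero net NADH drift in resting cells) has
#' the unique solution `v2 = v3 = (|v1| - v4)/2`. This is the computation
#' that yields the maximum specific 3HP and 1,3PDO production rates from
#' measured uptake and accumulation rates.
#'
#' @param v1 Glycerol uptake flux in mmol/g_CDW.h (negative by the
#'   consumption convention; a magnitude is also accepted).
#' @param v4 Net 3HPA accumulation flux in mmol/g_CDW.h, `0 <= v4 <= |v1|`.
#' @param network A `pdu_network`.
#' @return A `flux_vector` with `v1` stored negative and `v2 = v3`.
#' @examples
#' f <- infer_branch_fluxes(-2.891, 0.391)
#' f$molar[c("v2", "v3")]   # both 1.250
#' @export
infer_branch_fluxes <- function(v1, v4, network = build_pdu_network()) {
  if (v4 < 0 || v4 > abs(v1))
    stop("infeasible fluxes: need 0 <= v4 <= |v1| (got v4 = ", v4,
         ", |v1| = ", abs(v1), ")")
  b <- (abs(v1) - v4) / 2
  flux_vector(v1 = -abs(v1), v2 = b, v3 = b, v4 = v4, units = "mmol",
              network = network)
}

#' Write a network definition to a YAML file
#'
#' Serializes a `pdu_network` in the structured format accepted by
#' [build_pdu_network()].
#'
#' @param network A `pdu_network`.
#' @param path Output file path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_pdu_network <- function(network, path) {
  met <- lapply(seq_len(nrow(network$metabolites)), function(i) {
    m <- network$metabolites[i, ]
    list(id = m$id, name = m$name, molar_mass = m$molar_mass, role = m$role)
  })
  st <- lapply(colnames(network$stoich), function(r) {
    col <- network$stoich[, r]
    as.list(col[col != 0])
  })
  names(st) <- colnames(network$stoich)
  write_structured_config(list(metabolites = met, stoichiometry = st), path)
  invisible(path)
}
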