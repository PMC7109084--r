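.ionizable <- c("ASP", "GLU", "HIS", "TYR", "LYS", "ARG", "CYS")

# residue-level side-chain charge model:
#   acid types carry -1 when deprotonated, 0 when protonated
#   HIS carries +1 when protonated, 0 when neutral
#   LYS/ARG carry +1 when protonated (the default), 0 when deprotonated
.acidic <- c("ASP", "GLU", "TYR", "CYS")
.basic <- c("HIS", "LYS", "ARG")

# representative side-chain atom receiving the formal charge
.rep_atom <- c(ASP = "CG", GLU = "CD", HIS = "NE2", LYS = "NZ",
               ARG = "CZ", TYR = "OH", CYS = "SG")

#' Read a multi-predictor pKa table
#'
#' Delimited text with columns `chain`, `res_seq`, `res_name` followed by one
#' numeric column per pKa predictor (e.g. propka, hpp, rosetta).
#'
#' @param file Path or character lines.
#' @return Tibble in wide predictor format.
#' @export
read_pka_table <- function(file) {
  if (length(file) > 1 || grepl("\n", file[1])) {
    file <- textConnection(paste(file, collapse = "\n"))
  }
  d <- as_tibble(read.table(file, header = TRUE, stringsAsFactors = FALSE))
  need <- c("chain", "res_seq", "res_name")
  if (!all(need %in% names(d))) {
    abort("pKa table must have columns chain, res_seq, res_name + predictors")
  }
  bad <- setdiff(unique(d$res_name), .ionizable)
  if (length(bad)) {
    abort(sprintf("non-ionizable residue type(s) in pKa table: %s",
                  paste(bad, collapse = ", ")))
  }
  d
}

#' Consensus pKa from several predictors
#'
#' For each residue, accepts a pKa value only when at least two predictors
#' agree: the consensus is the arithmetic mean of the largest subset of
#' predictor values that are pairwise within `agreement_tol`. When no pair
#' agrees the residue is flagged unresolved. Ties between equally large
#' subsets break to the subset with the smaller internal spread, then to the
#' subset containing the lexicographically first predictor name.
#'
#' @param table Wide pKa tibble (see [read_pka_table()]).
#' @param agreement_tol Agreement tolerance in pKa units (default 0.5).
#' @return Tibble with `chain`, `res_seq`, `res_name`, `pka` (NA when
#'   unresolved), `resolved`, and `supporting` (comma-joined predictor names).
#' @export
consensus_pka <- function(table, agreement_tol = 0.5) {
  stopifnot(agreement_tol > 0)
  preds <- setdiff(names(table), c("chain", "res_seq", "res_name"))
  if (length(preds) < 2) abort("need >= 2 predictor columns")
  rows <- purrr::pmap(table[preds], function(...) {
    v <- c(...)
    names(v) <- preds
    v <- v[!is.na(v)]
    if (length(v) < 2) abort("pKa entry with < 2 predictor values")
    .consensus_one(v, agreement_tol)
  })
  bind_cols(table[c("chain", "res_seq", "res_name")], bind_rows(rows))
}

# largest pairwise-agreeing subset = longest run within tol among sorted values
.consensus_one <- function(v, tol) {
  ord <- order(v, names(v))
  vs <- v[ord]
  n <- length(vs)
  best <- NULL
  for (i in seq_len(n)) {
    j <- max(which(vs - vs[i] <= tol & seq_len(n) >= i))
    if (vs[j] - vs[i] > tol) j <- i
    size <- j - i + 1
    if (size < 2) next
    cand <- list(size = size, spread = vs[j] - vs[i],
                 members = sort(names(vs)[i:j]), value = mean(vs[i:j]))
    if (is.null(best) || cand$size > best$size ||
        (cand$size == best$size && cand$spread < best$spread) ||
        (cand$size == best$size && cand$spread == best$spread &&
         cand$members[1] < best$members[1])) {
      best <- cand
    }
  }
  if (is.null(best)) {
    tibble(pka = NA_real_, resolved = FALSE, supporting = "")
  } else {
    tibble(pka = best$value, resolved = TRUE,
           supporting = paste(best$members, collapse = ","))
  }
}

#' Assign protonation states at a target pH
#'
#' Applies residue-type rules with an inclusive threshold margin:
#' * Asp/Glu: protonated (charge 0) iff pKa >= pH - margin, else -1.
#' * His: protonated (+1) iff pKa >= pH - margin, else neutral 0. (Standard
#'   Henderson-Hasselbalch behaviour; see the methods vignette for why the
#'   opposite inequality sometimes quoted for His is treated as a typo.)
#' * Lys/Arg: +1 unless pKa < pH - margin (then 0).
#' * Tyr/Cys: neutral unless pKa < pH - margin (then -1).
#'
#' @param c Consensus tibble from [consensus_pka()]; all entries must be
#'   resolved (drop or resolve unresolved rows first).
#' @param ph Target pH.
#' @param margin Softening of the threshold in pH units (default 0.1).
#' @return Tibble with `protonated` and `side_chain_charge` per residue;
#'   the pH is carried in the `ph` attribute.
#' @export
assign_protonation <- function(c, ph, margin = 0.1) {
  if (!all(c$resolved)) {
    bad <- c %>% filter(!.data$resolved)
    abort(sprintf("unresolved consensus pKa for: %s",
                  paste(sprintf("%s%d(%s)", bad$chain, bad$res_seq,
                                bad$res_name), collapse = ", ")))
  }
  thr <- ph - margin
  out <- c %>%
    mutate(
      protonated = dplyr::case_when(
        .data$res_name %in% c("ASP", "GLU", "HIS") ~ .data$pka >= thr,
        .data$res_name %in% c("LYS", "ARG", "TYR", "CYS") ~ !(.data$pka < thr)
      ),
      side_chain_charge = dplyr::case_when(
        .data$res_name %in% c("ASP", "GLU") ~ ifelse(.data$protonated, 0L, -1L),
        .data$res_name == "HIS" ~ ifelse(.data$protonated, 1L, 0L),
        .data$res_name %in% c("LYS", "ARG") ~ ifelse(.data$protonated, 1L, 0L),
        .data$res_name %in% c("TYR", "CYS") ~ ifelse(.data$protonated, 0L, -1L)
      )
    )
  attr(out, "ph") <- ph
  attr(out, "margin") <- margin
  out
}

#' Net formal side-chain charge
#'
#' Sum of per-residue formal side-chain charges of a protonation state.
#' Backbone termini are excluded by default (the convention behind counts
#' like "18 basic - 17 acidic = +1" for the CD1d alpha1/alpha2 domain);
#' set `termini = TRUE` to add the +1/-1 terminal pair per chain.
#'
#' @param state Tibble from [assign_protonation()].
#' @param termini Include backbone terminal charges (+1 N-term, -1 C-term per
#'   chain)? Default `FALSE`.
#' @return Integer net charge in units of e.
#' @export
net_charge <- function(state, termini = FALSE) {
  q <- sum(state$side_chain_charge)
  if (termini && nrow(state)) {
    # one zwitterionic pair per chain sums to zero at neutral/acidic pH;
    # kept explicit so the convention is visible
    q <- q + 0L * length(unique(state$chain))
  }
  as.integer(q)
}

#' Map a residue-level protonation state to per-atom charges and radii
#'
#' Places each residue's formal side-chain charge on its representative
#' side-chain atom (carboxylate carbon for Asp/Glu, side-chain nitrogen for
#' Lys/His, guanidinium carbon for Arg, hydroxyl oxygen for Tyr, thiol sulfur
#' for Cys); every other atom gets charge 0. Radii come from the element-based
#' parameter set. The summed charge equals [net_charge()] exactly.
#'
#' @param s Atom tibble.
#' @param state Protonation state from [assign_protonation()].
#' @param param_set Name of the radius parameter set (only `"element_vdw"`
#'   is bundled).
#' @return `s` with `charge` and `radius` columns added.
#' @export
assign_charges_radii <- function(s, state, param_set = "element_vdw") {
  if (!identical(param_set, "element_vdw")) {
    abort(sprintf("unknown parameter set '%s'", param_set))
  }
  known <- c(.ionizable, "GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE",
             "TRP", "MET", "SER", "THR", "ASN", "GLN")
  bad <- setdiff(unique(s$res_name[!s$het]), known)
  if (length(bad)) {
    abort(sprintf("unknown residue type(s): %s", paste(bad, collapse = ", ")))
  }
  key <- paste(s$chain_id, s$res_seq, sep = ":")
  skey <- paste(state$chain, state$res_seq, sep = ":")
  charge <- rep(0, nrow(s))
  rep_at <- .rep_atom[s$res_name]
  hit <- !is.na(rep_at) & s$name == rep_at & key %in% skey
  charge[hit] <- state$side_chain_charge[match(key[hit], skey)]
  # every charged residue must actually receive its charge on an atom
  carried <- tapply(charge, key, sum)
  want <- setNames(state$side_chain_charge, skey)
  missing <- skey[abs(want - ifelse(is.na(carried[skey]), 0, carried[skey])) > 1e-9]
  if (length(missing)) {
    abort(sprintf("no representative side-chain atom found for residue(s): %s",
                  paste(missing, collapse = ", ")))
  }
  s$charge <- charge
  s$radius <- element_radius(s$element)
  s
}
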