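#' Geometric interaction criteria
#'
#' Defaults follow the published PLIP geometric defaults: hydrogen bond
#' donor-acceptor heavy-atom distance at most 0.41 nm with a donor-H...A
#' angle of at least 100 degrees; hydrophobic carbon-carbon contact at most
#' 0.40 nm; salt-bridge charged-group centroid separation at most 0.55 nm.
#'
#' @param hbond_dist nm; @param hbond_angle degrees in (0, 180];
#' @param hydrophobic_dist nm; @param saltbridge_dist nm.
#' @return list of class `"interaction_criteria"`.
#' @export
interaction_criteria <- function(hbond_dist = 0.41, hbond_angle = 100,
                                 hydrophobic_dist = 0.40,
                                 saltbridge_dist = 0.55) {
  stopifnot(hbond_dist > 0, hydrophobic_dist > 0, saltbridge_dist > 0,
            hbond_angle > 0, hbond_angle <= 180)
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 hydrophobic_dist = hydrophobic_dist,
                 saltbridge_dist = saltbridge_dist),
            class = "interaction_criteria")
}

# Covalent connectivity inferred from geometry of one frame: hydrogens bind
# their nearest heavy atom within 0.13 nm; heavy-heavy bonds within 0.18 nm.
covalent_neighbours <- function(top, xyz, h_max = 0.13, heavy_max = 0.18) {
  a <- top$atoms
  n <- nrow(a)
  heavy <- which(a$heavy)
  hyd <- which(!a$heavy)
  h_parent <- rep(NA_integer_, n)
  for (h in hyd) {
    d2 <- rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[h, ])^2)
    j <- which.min(d2)
    if (length(j) && d2[j] <= h_max^2) h_parent[h] <- heavy[j]
  }
  heavy_nb <- vector("list", n)
  if (length(heavy) > 1) {
    hx <- xyz[heavy, , drop = FALSE]
    dm <- as.matrix(stats::dist(hx))
    for (k in seq_along(heavy)) {
      nb <- heavy[dm[k, ] > 0 & dm[k, ] <= heavy_max]
      heavy_nb[[heavy[k]]] <- nb
    }
  }
  list(h_parent = h_parent, heavy_nb = heavy_nb)
}

# residue-pair key helpers: partners are residue ids as character, or the
# ligand residue name.
partner_id <- function(top, atom_idx) {
  a <- top$atoms
  if (!is.null(top$ligand) && a$resname[atom_idx] == top$ligand) {
    top$ligand
  } else {
    as.character(a$resid[atom_idx])
  }
}

is_seq_neighbour <- function(top, i, j) {
  a <- top$atoms
  lig <- function(k) !is.null(top$ligand) && a$resname[k] == top$ligand
  if (lig(i) || lig(j)) return(FALSE)
  a$chain[i] == a$chain[j] && abs(a$resid[i] - a$resid[j]) <= 1
}

#' Detect hydrogen bonds in one frame
#'
#' A donor-acceptor pair is reported when the donor heavy atom (N/O/S with
#' at least one covalently attached hydrogen) lies within
#' `criteria$hbond_dist` of an acceptor (N/O of another residue) and the
#' donor-H...acceptor angle at the hydrogen is at least
#' `criteria$hbond_angle`. One record per residue pair per frame.
#'
#' @param top a [topology()]; must contain explicit hydrogens (MD
#'   topologies do) — no implicit hydrogen placement is performed.
#' @param xyz `atoms x 3` coordinates, nm.
#' @param criteria an [interaction_criteria()].
#' @param bonds optional precomputed [covalent_neighbours()] result.
#' @param exclude_neighbours drop residue-residue pairs with
#'   `|delta resid| <= 1` on the same chain (ligand pairs always kept).
#' @return data.frame `res_a` (donor partner), `res_b` (acceptor partner),
#'   `donor_atom`, `acceptor_atom`.
#' @export
detect_hbonds <- function(top, xyz, criteria = interaction_criteria(),
                          bonds = NULL, exclude_neighbours = TRUE) {
  a <- top$atoms
  if (!any(!a$heavy)) {
    stop("no-hydrogen topology: hydrogen-bond detection needs explicit ",
         "hydrogens")
  }
  if (is.null(bonds)) bonds <- covalent_neighbours(top, xyz)
  donors <- which(a$elem %in% c("N", "O", "S") & a$heavy)
  donors <- donors[vapply(donors, function(d) {
    any(bonds$h_parent == d, na.rm = TRUE)
  }, logical(1))]
  acceptors <- which(a$elem %in% c("N", "O") & a$heavy)
  out <- list()
  seen <- character(0)
  for (d in donors) {
    hs <- which(bonds$h_parent == d)
    for (acc in acceptors) {
      if (acc == d) next
      same_res <- a$resid[acc] == a$resid[d] & a$chain[acc] == a$chain[d]
      if (same_res) next
      if (exclude_neighbours && is_seq_neighbour(top, d, acc)) next
      dd <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
      if (dd > criteria$hbond_dist) next
      for (h in hs) {
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[acc, ] - xyz[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang >= criteria$hbond_angle) {
          pa <- partner_id(top, d)
          pb <- partner_id(top, acc)
          key <- paste(sort(c(pa, pb)), collapse = "|")
          if (!key %in% seen) {
            seen <- c(seen, key)
            out[[length(out) + 1]] <- data.frame(
              res_a = pa, res_b = pb,
              donor_atom = a$name[d], acceptor_atom = a$name[acc],
              stringsAsFactors = FALSE)
          }
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(res_a = character(0), res_b = character(0),
                      donor_atom = character(0),
                      acceptor_atom = character(0)))
  }
  do.call(rbind, out)
}

#' Detect hydrophobic contacts in one frame
#'
#' Apolar carbons are carbons whose covalent heavy-atom neighbours are all
#' carbon. A residue pair is reported when any apolar-carbon pair lies
#' within `criteria$hydrophobic_dist`.
#'
#' @inheritParams detect_hbonds
#' @return data.frame `res_a`, `res_b`.
#' @export
detect_hydrophobic <- function(top, xyz, criteria = interaction_criteria(),
                               bonds = NULL, exclude_neighbours = TRUE) {
  a <- top$atoms
  if (is.null(bonds)) bonds <- covalent_neighbours(top, xyz)
  apolar <- which(a$elem == "C" & vapply(seq_len(nrow(a)), function(i) {
    nb <- bonds$heavy_nb[[i]]
    length(nb) == 0 || all(a$elem[nb] == "C")
  }, logical(1)))
  out <- character(0)
  rows <- list()
  if (length(apolar) >= 2) {
    dm <- as.matrix(stats::dist(xyz[apolar, , drop = FALSE]))
    hits <- which(dm <= criteria$hydrophobic_dist & upper.tri(dm),
                  arr.ind = TRUE)
    for (r in seq_len(nrow(hits))) {
      i <- apolar[hits[r, 1]]
      j <- apolar[hits[r, 2]]
      if (a$resid[i] == a$resid[j] && a$chain[i] == a$chain[j]) next
      if (exclude_neighbours && is_seq_neighbour(top, i, j)) next
      pa <- partner_id(top, i)
      pb <- partner_id(top, j)
      key <- paste(sort(c(pa, pb)), collapse = "|")
      if (!key %in% out) {
        out <- c(out, key)
        rows[[length(rows) + 1]] <- data.frame(res_a = pa, res_b = pb,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(res_a = character(0), res_b = character(0)))
  }
  do.call(rbind, rows)
}

# charged side-chain groups by residue name (atom-name sets and sign)
.charged_groups <- list(
  ASP = list(atoms = c("OD1", "OD2"), charge = -1),
  GLU = list(atoms = c("OE1", "OE2"), charge = -1),
  LYS = list(atoms = "NZ", charge = +1),
  ARG = list(atoms = c("NE", "NH1", "NH2"), charge = +1),
  HIS = list(atoms = c("ND1", "NE2"), charge = +1)
)

charged_group_table <- function(top, xyz) {
  res <- top$residues
  groups <- list()
  for (r in seq_len(nrow(res))) {
    rn <- res$resname[r]
    if (!is.null(top$ligand) && rn == top$ligand) {
      if (is.null(top$ligand_charges)) {
        stop("configuration error: ligand '", top$ligand,
             "' present but its charged groups are undeclared ",
             "(pass ligand_charges, possibly an empty list)")
      }
      for (g in top$ligand_charges) {
        idx <- select_atoms(top, resid = res$resid[r], name = g$atoms)
        if (length(idx) == 0) next
        groups[[length(groups) + 1]] <-
          list(partner = rn, charge = g$charge,
               centroid = colMeans(xyz[idx, , drop = FALSE]))
      }
    } else if (rn %in% names(.charged_groups)) {
      g <- .charged_groups[[rn]]
      idx <- select_atoms(top, resid = res$resid[r], name = g$atoms)
      if (length(idx) == 0) next
      groups[[length(groups) + 1]] <-
        list(partner = as.character(res$resid[r]), charge = g$charge,
             centroid = colMeans(xyz[idx, , drop = FALSE]))
    }
  }
  groups
}

#' Detect salt bridges in one frame
#'
#' Oppositely charged group centroids (Asp/Glu carboxylates vs
#' Lys/Arg/His cationic groups, plus declared ligand charge groups) within
#' `criteria$saltbridge_dist` are reported, one record per residue pair.
#'
#' @inheritParams detect_hbonds
#' @return data.frame `res_a`, `res_b`.
#' @export
detect_saltbridges <- function(top, xyz, criteria = interaction_criteria(),
                               bonds = NULL, exclude_neighbours = TRUE) {
  groups <- charged_group_table(top, xyz)
  rows <- list()
  seen <- character(0)
  if (length(groups) >= 2) {
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        gi <- groups[[i]]; gj <- groups[[j]]
        if (gi$charge * gj$charge >= 0) next
        if (gi$partner == gj$partner) next
        d <- sqrt(sum((gi$centroid - gj$centroid)^2))
        if (d > criteria$saltbridge_dist) next
        key <- paste(sort(c(gi$partner, gj$partner)), collapse = "|")
        if (!key %in% seen) {
          seen <- c(seen, key)
          rows[[length(rows) + 1]] <- data.frame(res_a = gi$partner,
                                                 res_b = gj$partner,
                                                 stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(res_a = character(0), res_b = character(0)))
  }
  do.call(rbind, rows)
}

#' Interaction probabilities over a trajectory
#'
#' Runs the geometric detectors on every frame and reports, for each
#' (type, partner pair) observed at least once, the fraction of frames in
#' which the interaction is present — the standard per-frame occupancy
#' definition of an interaction probability.
#'
#' @param traj a [trajectory()].
#' @param focus optional partner to restrict to: a residue index, or the
#'   ligand residue name.
#' @param criteria an [interaction_criteria()].
#' @param types subset of `c("hbond", "hydrophobic", "saltbridge")`.
#' @param exclude_neighbours see [detect_hbonds()].
#' @return data.frame of class `"interaction_records"` with columns `type`,
#'   `partner_a`, `partner_b`, `probability`, `n_frames`, sorted by
#'   decreasing probability (stable); per-record presence bit vectors in
#'   `attr(, "presence")`.
#' @export
interaction_probabilities <- function(traj, focus = NULL,
                                      criteria = interaction_criteria(),
                                      types = c("hbond", "hydrophobic",
                                                "saltbridge"),
                                      exclude_neighbours = TRUE) {
  nf <- n_frames(traj)
  stopifnot(nf >= 1)
  top <- traj$top
  bonds <- covalent_neighbours(top, frame_coords(traj, 1))
  has_h <- any(!top$atoms$heavy)
  records <- new.env(parent = emptyenv())
  note <- function(type, pa, pb, f) {
    key <- paste(type, paste(sort(c(pa, pb)), collapse = "|"), sep = "|")
    rec <- records[[key]]
    if (is.null(rec)) {
      rec <- list(type = type, a = pa, b = pb, present = logical(nf))
    }
    rec$present[f] <- TRUE
    records[[key]] <- rec
  }
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    if ("hbond" %in% types && has_h) {
      hb <- detect_hbonds(top, xyz, criteria, bonds, exclude_neighbours)
      for (r in seq_len(nrow(hb))) note("hbond", hb$res_a[r], hb$res_b[r], f)
    }
    if ("hydrophobic" %in% types) {
      hp <- detect_hydrophobic(top, xyz, criteria, bonds, exclude_neighbours)
      for (r in seq_len(nrow(hp))) {
        note("hydrophobic", hp$res_a[r], hp$res_b[r], f)
      }
    }
    if ("saltbridge" %in% types) {
      sb <- detect_saltbridges(top, xyz, criteria, bonds, exclude_neighbours)
      for (r in seq_len(nrow(sb))) {
        note("saltbridge", sb$res_a[r], sb$res_b[r], f)
      }
    }
  }
  keys <- ls(records)
  if (!is.null(focus)) {
    fid <- as.character(focus)
    keys <- keys[vapply(keys, function(k) {
      rec <- records[[k]]
      rec$a == fid || rec$b == fid
    }, logical(1))]
  }
  df <- do.call(rbind, lapply(keys, function(k) {
    rec <- records[[k]]
    data.frame(type = rec$type, partner_a = rec$a, partner_b = rec$b,
               probability = mean(rec$present), n_frames = nf,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(type = character(0), partner_a = character(0),
                     partner_b = character(0), probability = numeric(0),
                     n_frames = integer(0))
  }
  ord <- order(-df$probability)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "presence") <- lapply(keys[ord], function(k) records[[k]]$present)
  class(df) <- c("interaction_records", "data.frame")
  df
}

#' Filter interaction records by probability
#'
#' Keeps records with probability strictly greater than the threshold.
#' Given a list of record sets from several systems, a pair is kept in
#' every system if it passes the threshold in at least one of them (the
#' union rule used when comparing e.g. ligand-bound and ligand-free
#' states).
#'
#' @param records an `interaction_records` data.frame, or a list of them.
#' @param min_probability threshold in `[0, 1]`; strict inequality.
#' @return filtered records (same shape as the input).
#' @export
filter_records <- function(records, min_probability) {
  stopifnot(min_probability >= 0, min_probability <= 1)
  key_of <- function(df) {
    paste(df$type,
          ifelse(df$partner_a < df$partner_b,
                 paste(df$partner_a, df$partner_b),
                 paste(df$partner_b, df$partner_a)))
  }
  if (is.data.frame(records)) {
    out <- records[records$probability > min_probability, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  passing <- unique(unlist(lapply(records, function(df) {
    key_of(df)[df$probability > min_probability]
  })))
  lapply(records, function(df) {
    out <- df[key_of(df) %in% passing, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
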