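makeRankedSet <- function(nLig = 100, nPose = 3, seed = 5) {
  set.seed(seed)
  lig <- sprintf("lig%03d", seq_len(nLig))
  rows <- expand.grid(ligand_id = lig, pose = seq_len(nPose),
                      stringsAsFactors = FALSE)
  rows$pose_id <- sprintf("%s_conf_%02d", rows$ligand_id, rows$pose)
  rows$score <- runif(nrow(rows))
  rows$is_active <- TRUE
  entries <- lapply(seq_len(nrow(rows)), function(k)
    randomEntry(rows$pose_id[k], 4, seed = 1000 + k))
  list(entries = entries,
       ranking = rows[, c("ligand_id", "pose_id", "score", "is_active")])
}

test_that("top-active selection returns one best pose per top ligand", {
  rs <- makeRankedSet(100)
  sel <- selectTopActives(rs$entries, rs$ranking, nLigands = 50)
  expect_length(sel, 50)
  nm <- vapply(sel, function(e) e@name, character(1))
  lig <- sub("_conf_[0-9]+$", "", nm)
  expect_false(anyDuplicated(lig) > 0)
  # each selected pose is its ligand's best-scoring pose
  for (k in seq_along(sel)) {
    sub <- rs$ranking[rs$ranking$ligand_id == lig[k], ]
    expect_equal(nm[k], sub$pose_id[which.max(sub$score)])
  }
  # and the selected ligands are the 50 best by best-pose score
  best <- tapply(rs$ranking$score, rs$ranking$ligand_id, max)
  expect_setequal(lig, names(sort(best, decreasing = TRUE))[1:50])
})

test_that("asking for more actives than exist returns all with a warning", {
  rs <- makeRankedSet(10)
  expect_warning(sel <- selectTopActives(rs$entries, rs$ranking, nLigands = 50),
                 "only 10")
  expect_length(sel, 10)
})

test_that("selection is deterministic under score ties and input shuffling", {
  rs <- makeRankedSet(20)
  rs$ranking$score <- 1  # all tied: order must fall back to ligand_id
  sel1 <- selectTopActives(rs$entries, rs$ranking, nLigands = 5)
  set.seed(9)
  perm <- sample(nrow(rs$ranking))
  sel2 <- selectTopActives(rs$entries, rs$ranking[perm, ], nLigands = 5)
  expect_equal(vapply(sel1, function(e) e@name, character(1)),
               vapply(sel2, function(e) e@name, character(1)))
})

test_that("unresolvable pose entries are an error naming the ligand", {
  rs <- makeRankedSet(5)
  sub <- rs$ranking[rs$ranking$ligand_id == "lig001", ]
  best <- sub$pose_id[which.max(sub$score)]
  nm <- vapply(rs$entries, function(e) e@name, character(1))
  expect_error(selectTopActives(rs$entries[nm != best], rs$ranking,
                                nLigands = 5), "lig001")
})

test_that("non-polar hydrogen stripping keeps polar H and heavy atoms", {
  got <- stripNonpolarHydrogens(methanolEntry())
  expect_equal(nAtoms(got), 3L)  # C, O, and the O-H
  expect_setequal(got@atoms$name, c("C1", "O1", "H4"))
  # entry without hydrogens is untouched
  e <- randomEntry("noH", 5, 41)
  expect_equal(atoms(stripNonpolarHydrogens(e)), atoms(e))
})

test_that("hydrogens on nitrogen are retained", {
  atoms <- data.frame(atom_id = 1:2, name = c("N1", "H1"),
                      sybyl_type = c("N.3", "H"),
                      x = c(0, 1.0), y = 0, z = 0, charge = c(-0.5, 0.3))
  bonds <- data.frame(from = 1, to = 2, order = "1")
  e <- new("Mol2Molecule", name = "amine", atoms = atoms, bonds = bonds)
  expect_equal(nAtoms(stripNonpolarHydrogens(e)), 2L)
})

test_that("bond-less hydrogens are classified by the nearest heavy atom", {
  atoms <- data.frame(atom_id = 1:4, name = c("C1", "N1", "HC", "HFAR"),
                      sybyl_type = c("C.3", "N.3", "H", "H"),
                      x = c(0, 5, 1.0, 10), y = 0, z = 0,
                      charge = 0)
  e <- new("Mol2Molecule", name = "free", atoms = atoms,
           bonds = data.frame(from = integer(0), to = integer(0),
                              order = character(0)))
  expect_warning(got <- stripNonpolarHydrogens(e), "cannot classify")
  # HC (1.0 A from C) removed; HFAR unclassifiable and retained
  expect_setequal(got@atoms$name, c("C1", "N1", "HFAR"))
})

test_that("stripping never removes heavy atoms and never grows the entry", {
  for (seed in 1:5) {
    e <- randomEntry(paste0("p", seed), 8, seed)
    got <- stripNonpolarHydrogens(e)
    expect_lte(nAtoms(got), nAtoms(e))
    heavy_in <- sum(!grepl("^H", e@atoms$sybyl_type))
    heavy_out <- sum(!grepl("^H", got@atoms$sybyl_type))
    expect_equal(heavy_out, heavy_in)
  }
})

test_that("merging concatenates atoms, drops bonds, and conserves charge", {
  entries <- lapply(1:50, function(k) randomEntry(paste0("e", k), 20, k))
  cloud <- mergeToCloud(entries)
  expect_equal(nAtoms(cloud), 1000L)
  expect_equal(sum(atoms(cloud)$charge),
               sum(vapply(entries, function(e) sum(e@atoms$charge), numeric(1))))
  expect_false("bonds" %in% names(atoms(cloud)))
  # provenance: each source entry contributes its own atom count
  expect_equal(unname(table(atoms(cloud)$source_entry)["e1"]), 20L)
  single <- mergeToCloud(entries[[1]])
  expect_equal(nAtoms(single), 20L)
})

test_that("pocket limiting keeps atoms within the radius of the nearest reference heavy atom", {
  ref <- mol2Molecule("ref", data.frame(
    sybyl_type = c("C.3", "H"), x = c(0, 50), y = 0, z = 0, charge = 0))
  cloud <- testCloud(rbind(c(1.9, 0, 0), c(2.1, 0, 0), c(49, 0, 0)))
  got <- limitByReference(cloud, ref, 2.0)
  # reference hydrogens are ignored: the atom near x=49 must go
  expect_equal(atoms(got)$x, 1.9)
  expect_equal(nAtoms(limitByReference(cloud, ref, Inf)), 3L)
  expect_error(limitByReference(testCloud(rbind(c(99, 0, 0))), ref, 2.0),
               "larger radius")
})

test_that("pocket limiting matches a brute-force all-pairs filter and is idempotent", {
  set.seed(77)
  cloud <- randomCloud(200, seed = 77, box = 10)
  ref <- randomEntry("ref", 6, seed = 78, box = 10)
  got <- limitByReference(cloud, ref, 2.5)
  # independent O(n*m) oracle
  ra <- ref@atoms[!grepl("^H", ref@atoms$sybyl_type), ]
  df <- atoms(cloud)
  keep <- vapply(seq_len(nrow(df)), function(i)
    min(sqrt((ra$x - df$x[i])^2 + (ra$y - df$y[i])^2 + (ra$z - df$z[i])^2)) <= 2.5,
    logical(1))
  expect_equal(atoms(got), `rownames<-`(df[keep, ], NULL))
  expect_equal(atoms(limitByReference(got, ref, 2.5)), atoms(got))
})
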