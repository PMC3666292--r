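test_that("conformational propensities follow the pooled-count definition", {
  ct <- conformation_parameters("AAA", "HHC")
  expect_equal(unname(ct$S["A", ]), c(2 / 3, 0, 1 / 3))
  expect_true(all(ct$flagged[setdiff(rownames(ct$S), "A")]))
  expect_equal(unname(ct$S["G", ]), rep(1 / 3, 3))   # flagged-uniform row
  # counts retained and consistent: S * a_i == a_ij exactly
  expect_equal(ct$S["A", ] * ct$a_i[["A"]], ct$a_ij["A", ] + 0)

  # pooling over several chains
  ct2 <- conformation_parameters(c("AG", "GA"), c("HE", "CH"))
  expect_equal(unname(ct2$S["A", ]), c(1, 0, 0))
  expect_equal(unname(ct2$S["G", ]), c(0, 0.5, 0.5))
  expect_true(all(abs(rowSums(ct2$S) - 1) < 1e-9))

  expect_error(conformation_parameters(character(0), character(0)),
               "no chains")
  expect_error(conformation_parameters("AAAA", "HHC"), "chain 1")
})

test_that("the packaged reference table matches its source values", {
  S <- reference_conformation()$S
  expect_equal(unname(S["A", ]), c(0.49, 0.16, 0.35))
  expect_equal(unname(S["V", ]), c(0.30, 0.41, 0.29))
  expect_equal(dim(S), c(20L, 3L))
})

test_that("physicochemical lookups return the table values", {
  expect_equal(lookup_physico("R")[["charge"]], 1)
  expect_equal(lookup_physico("D")[["charge"]], -1)
  expect_equal(lookup_physico("I")[["hydropathy"]], 4.5)
  expect_equal(lookup_physico("G")[["mass"]], 1.0079)
  expect_equal(lookup_physico("W")[["mass"]], 130.1689)
  expect_error(lookup_physico("X", policy = "strict"), "unknown residue")
  expect_equal(lookup_physico("X")[["charge"]], 0)   # default policy
})

test_that("window encoding has dimension 20*ws+6 for every window size", {
  chain <- "MFKVYGYDSNIHKCVYCDNAKRLL"
  prof <- normalize_profile(synthesize_pssm(chain, 0.8, 3))
  ct <- reference_conformation()
  dims <- c(`7` = 146, `9` = 186, `11` = 226, `13` = 266, `15` = 306,
            `17` = 346, `19` = 386)
  for (ws in as.integer(names(dims))) {
    X <- encode_windows(chain, prof, ct, ws)
    expect_equal(ncol(X), 20L * ws + 6L)
    expect_equal(ncol(X), unname(dims[as.character(ws)]))
    expect_equal(nrow(X), nchar(chain))
    expect_true(all(X >= 0 & X <= 1))
  }
  expect_error(encode_windows(chain, prof, ct, ws = 8), "ws")
})

test_that("terminal windows are padded and scalars describe the centre", {
  prof <- normalize_profile(synthesize_pssm("M", 1, 2))
  ct <- reference_conformation()
  X <- encode_windows("M", prof, ct, ws = 7)
  expect_equal(dim(X), c(1L, 146L))
  expect_equal(unname(X[1, 1:60]), rep(0, 60))        # 3 left pad blocks
  expect_equal(unname(X[1, 81:140]), rep(0, 60))      # 3 right pad blocks
  expect_equal(unname(X[1, 61:80]), unname(prof$scores[1, ]))
  pt <- physico_tables()
  expect_equal(unname(X[1, 141:146]),
               c(unname(ct$S["M", ]), 0.5,
                 (pt$hydropathy[["M"]] + 4.5) / 9,
                 (pt$side_chain_mass[["M"]] - 1.0079) / (130.1689 - 1.0079)))
  # half-value padding option
  Xh <- encode_windows("M", prof, ct, ws = 7, pad = "half")
  expect_equal(unname(Xh[1, 1:60]), rep(0.5, 60))
})

test_that("encoding is translation-consistent across window offsets", {
  chain <- "MFKVYGYDSNIHKCVYCDNA"
  prof <- normalize_profile(synthesize_pssm(chain, 0.5, 11))
  X <- encode_windows(chain, prof, reference_conformation(), ws = 9)
  half <- 4L
  centre_block <- function(i) X[i, (half * 20L + 1L):(half * 20L + 20L)]
  for (i in 3:10) {
    for (n in -2:2) {
      off_block <- X[i, ((half + n) * 20L + 1L):((half + n) * 20L + 20L)]
      expect_equal(unname(off_block), unname(centre_block(i + n)))
    }
  }
})

test_that("encoding rejects mismatched or unnormalized profiles", {
  prof <- synthesize_pssm("MFK", 1, 1)
  ct <- reference_conformation()
  expect_error(encode_windows("MFK", prof, ct, 7), "normalized")
  expect_error(encode_windows("MFKV", normalize_profile(prof), ct, 7),
               "4 residues")
})
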