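ref_query_pair <- function(seed = 81, n_genes = 30) {
  spec <- synthetic_spec(n_types = 2, n_batches = 4, cells_per_batch = 50,
                         n_genes = n_genes, de_genes_per_type = 4, seed = seed)
  ds <- normalize_lognorm(simulate_atlas(spec))
  holdout_split(ds, c("batch1", "batch2"))
}

trained_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- ref_query_pair()
      cache <<- list(split = sp,
                     model = train_reference(sp$reference,
                                             tiny_config(30, epochs = 12)))
    }
    cache
  }
})

test_that("expand_conditions appends adaptor rows and touches nothing else", {
  m <- trained_ref()$model
  m1 <- expand_conditions(m, "batch3")
  expect_identical(m1$registry, c(m$registry, "batch3"))
  expect_equal(nrow(m1$par$enc_s), 3)
  expect_equal(nrow(m1$par$dec_s), 3)
  # frozen contract: every pre-existing tensor bitwise equal
  for (nm in names(m$par)) {
    if (nm %in% c("enc_s", "dec_s")) {
      expect_identical(m1$par[[nm]][1:2, ], m$par[[nm]])
    } else {
      expect_identical(m1$par[[nm]], m$par[[nm]])
    }
  }
  expect_identical(expand_conditions(m, character(0)), m)
  expect_error(expand_conditions(m1, "batch3"), "already in registry")
})

test_that("freeze strategies mark exactly the intended parameters", {
  m <- expand_conditions(trained_ref()$model, c("batch3", "batch4"))
  p <- ncol(m$par$enc_s); q <- ncol(m$par$dec_s)
  ad <- set_freeze(m, "adaptors")
  expect_equal(count_trainable(ad), 2 * (p + q))
  expect_true(all(!ad$frozen$enc_s[3:4, ]))
  expect_true(all(ad$frozen$enc_s[1:2, ]))
  expect_true(all(ad$frozen$enc_x))
  fl <- set_freeze(m, "first_layers")
  expect_true(all(!fl$frozen$enc_x) && all(!fl$frozen$enc_s) &&
                all(!fl$frozen$dec_z) && all(!fl$frozen$dec_s))
  expect_true(all(fl$frozen$enc_W2) && all(fl$frozen$dec_W2) &&
                all(fl$frozen$enc_mu_W))
  full <- set_freeze(m, "full")
  expect_equal(count_trainable(full),
               sum(vapply(m$par, length, 1L)))
})

test_that("adaptor parameter count law m*(p+q) holds on a dimension grid", {
  for (m_new in c(1, 2)) for (p in c(8, 16)) for (q in c(8, 12)) {
    cfg <- model_config(10, latent_dim = 3, encoder_widths = c(p, 6),
                        decoder_widths = c(q, 6), epochs = 0, seed = 1)
    ds <- toy_dataset(n_cells = 12, n_genes = 10)
    mod <- train_reference(ds, cfg)
    mod <- expand_conditions(mod, paste0("new", seq_len(m_new)))
    mod <- set_freeze(mod, "adaptors")
    expect_equal(count_trainable(mod), m_new * (p + q))
  }
})

test_that("adaptors-mode fine-tuning leaves every frozen tensor byte-identical", {
  tr <- trained_ref()
  query <- subset_cells(tr$split$query,
                        tr$split$query$cell_meta$study == "batch3")
  m <- expand_conditions(tr$model, "batch3")
  m0 <- finetune_query(m, query, "adaptors", epochs = 0)
  expect_identical(m0$par, m$par)
  mt <- finetune_query(m, query, "adaptors", epochs = 8)
  for (nm in names(mt$par)) {
    if (nm %in% c("enc_s", "dec_s")) {
      expect_identical(mt$par[[nm]][1:2, ], m$par[[nm]][1:2, ])
      expect_false(identical(mt$par[[nm]][3, ], m$par[[nm]][3, ]))
    } else {
      expect_identical(mt$par[[nm]], m$par[[nm]])
    }
  }
  # reference embeddings unchanged by surgery
  e_before <- embed(tr$model, tr$split$reference)
  e_after <- embed(mt, tr$split$reference)
  expect_identical(e_before$coords, e_after$coords)
})

test_that("fine-tuning rejects reference studies and unaligned genes", {
  tr <- trained_ref()
  m <- expand_conditions(tr$model, "batch3")
  expect_error(finetune_query(m, tr$split$reference, "adaptors"),
               "reference study")
  query <- subset_cells(tr$split$query,
                        tr$split$query$cell_meta$study == "batch3")
  trimmed <- subset_genes(query, 1:29)
  expect_error(finetune_query(m, trimmed, "adaptors"), "align_genes")
  q4 <- subset_cells(tr$split$query,
                     tr$split$query$cell_meta$study == "batch4")
  expect_error(finetune_query(m, q4, "adaptors"), "not grafted")
})

test_that("adaptor training commutes across query studies", {
  tr <- trained_ref()
  qA <- subset_cells(tr$split$query,
                     tr$split$query$cell_meta$study == "batch3")
  qB <- subset_cells(tr$split$query,
                     tr$split$query$cell_meta$study == "batch4")
  base <- tr$model
  go <- function(first, second) {
    m <- expand_conditions(base, first$studies)
    m <- finetune_query(m, first, "adaptors", epochs = 6)
    m <- expand_conditions(m, second$studies)
    finetune_query(m, second, "adaptors", epochs = 6)
  }
  mAB <- go(qA, qB)
  mBA <- go(qB, qA)
  for (nm in names(mAB$par)) {
    a <- mAB$par[[nm]]
    b <- mBA$par[[nm]]
    if (nm %in% c("enc_s", "dec_s")) {
      rows <- match(mAB$registry, mBA$registry)
      expect_identical(a, b[rows, ])
    } else {
      expect_identical(a, b)
    }
  }
  both <- sc_dataset(counts = rbind(qA$counts, qB$counts),
                     lognorm = rbind(qA$lognorm, qB$lognorm),
                     genes = qA$genes,
                     cell_meta = rbind(qA$cell_meta, qB$cell_meta))
  eAB <- embed(mAB, both)
  eBA <- embed(mBA, both)
  expect_identical(eAB$coords, eBA$coords)
})
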