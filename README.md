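# fbanet

Automated screening of House-Tree-Person (HTP) sketches with a
feature-enhanced bi-level attention network, in pure R.

The HTP test asks a subject to draw a house, a tree and a person; clinicians
read stylistic markers — heavy dark strokes, bare or withered trees, falling
rain, cracked walls — as indicators of depressive state. This package
implements a one-stage deep classifier for such sketches and everything
around it: the patch-based feature enhancement, the bi-level attention
block, the transfer-learning protocol with stratified cross-validation,
confusion-matrix metrics, Grad-CAM saliency, synthetic corpus generators,
and a command-line interface. Every forward and backward pass is base R
matrix algebra — there is no deep-learning framework underneath.

## The model

A square sketch is covered by P ∈ {5, 9} overlapping square patches of side
⌊σW⌋ (σ = 0.6 for five patches — 36% of the image each — and σ = 0.4 for
nine — 16% each). Patches and the whole sketch pass through a shared
convolutional stem; the local features are averaged,

    F̂_L = (F_1 + … + F_P) / P,

concatenated with the global features F_G, and a 1×1 convolution adjusts the
channels to N, giving F_w ∈ R^{N×h×w}. Two attention readings of F_w are
fused: a token self-attention stack over the N channels (tokens of width
d = h·w, learnable positional encoding, L layers of
X ← X + MHSA(X); X ← X + MLP(LN(X))), and a triplet attention whose three
branches gate each pair of tensor dimensions through Zpool (max ‖ mean) →
7×7 convolution → batch norm → sigmoid. The fused block, compensated with a
projection of F_G, feeds a Conv → GAP → Linear head. Training follows a
two-phase transfer protocol: supervised pre-training on a many-class sketch
corpus (SGD, warmup–cosine schedule, base lr 3e-2), then five-fold
stratified fine-tuning on the binary clinical task (10 epochs per fold, base
lr 1e-3, flips + normalization, nothing frozen).

## Worked example

No clinical HTP corpus is public, so the example runs on the package's
synthetic corpora (see the methods vignette for what they do and do not
emulate). A desk-scale model is pre-trained on procedurally drawn glyphs,
then fine-tuned on two-class house-tree-person scenes whose depressed class
draws darker strokes and more depressive motifs:

```r
library(fbanet)

## many-class pre-training corpus (white strokes on black; inverted on load)
qd  <- generate_quickdraw_like(qd_gen_params(n_classes = 10, n_train = 60,
                                             n_val = 10, n_test = 10, seed = 0))
cfg <- fbanet_config(num_patches = 5, layers = 6, adjusted_channels = 16,
                     num_class = 10, input_side = 32, stem = "tiny", seed = 0)
pre <- run_pretrain(cfg, train_config("pretrain", epochs = 30, seed = 0), qd)
save_checkpoint(pre$model, "pretrained.rds")

## two-class HTP-like corpus, fine-tuned under the standard protocol
htp <- generate_htp_like(htp_gen_params(n_samples = 400, seed = 0))
cv  <- run_finetune(NULL, train_config("finetune", seed = 0), htp,
                    checkpoint = "pretrained.rds")
print(cv)
```

```
Stratified 5-fold cross-validation
fold 1 (best epoch 6): acc 0.8375  prec 0.8000  rec 0.2500  f1 0.3810
fold 2 (best epoch 8): acc 0.8625  prec 1.0000  rec 0.3125  f1 0.4762
fold 3 (best epoch 6): acc 0.8250  prec 1.0000  rec 0.0667  f1 0.1250
fold 4 (best epoch 6): acc 0.8500  prec 1.0000  rec 0.2500  f1 0.4000
fold 5 (best epoch 7): acc 0.8250  prec 1.0000  rec 0.1250  f1 0.2222
average: acc 0.8400  prec 0.9600  rec 0.2008  f1 0.3209
max:     acc 0.8625  prec 1.0000  rec 0.3125  f1 0.4762
```

Accuracy/precision/recall/F1 are computed from the fold's validation
confusion matrix with the depressed class as positive; `average`/`max`
aggregate the per-fold best epochs. Two things to read off this run. First,
the transfer phase matters: without pre-training the same fine-tune learns
only the 80/20 base rate (accuracy 0.80, recall 0). Second, desk scale has
limits: at this model size and pre-training budget the fine-tuned model
beats the base rate on every fold with near-perfect precision, but its
recall stays well below what full-scale pre-training achieves — the methods
vignette explains why (the prescribed 200 fine-tuning steps track the
transferred representation's linear separability, which a small glyph
pre-train leaves well short of the corpus's ceiling).

Saliency for a single sketch:

```r
hm <- grad_cam(cv$model, htp$images[[1]], target_class = 1, target_layer = "fusion")
save_overlay(hm, htp$images[[1]], "overlay.png", alpha = 0.5)
```

A thin CLI wraps the same functions
(`Rscript inst/cli/fbanet.R synth|pretrain|finetune|evaluate|gradcam ...`).

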