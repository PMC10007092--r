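# sswan

Semantic segmentation of 2D MRI brain-tumor slices with a wavelet-domain
attention network (SSW-AN), implemented as a pure-R package: the model,
its hand-derived training engine, Dice losses, a segmentation metric
suite, a synthetic tumor-phantom generator, NIfTI/PNG I/O and a command
line.

## The problem and the model

Gliomas in MRI have diffuse boundaries and low contrast, so per-pixel
(semantic) segmentation of tumor sub-regions is hard and noisy.  SSW-AN
attacks this in the wavelet domain.  For an input slice `F` the pipeline
is:

1. **Bicubic baseline.**  Downsample by a factor (default 2) and
   bicubically upsample back, giving a smooth baseline `F_bic`.
2. **Wavelet front end.**  A single-level orthonormal 2D DWT (Haar by
   default) splits `F_bic` into four half-resolution channels
   `(LL, LH, HL, HH)` — mean, vertical, horizontal and diagonal detail.
   The transform is invertible, so nothing is lost.
3. **Shallow extraction.**  `I_0 = LeakyReLU(conv5x5(·))` maps the four
   channels to `w` feature channels (Leaky because wavelet coefficients
   are signed).
4. **T attention blocks (SSABs).**  Each block applies a 3x3
   convolution, then *channel attention* — a per-channel sigmoid gate
   `M = sigmoid(MLP(maxpool) + MLP(avgpool))` with one shared
   bottleneck MLP (reduction ratio `h`) — then *spatial attention* — a
   per-position sigmoid gate from a 7x7 convolution of the
   channel-pooled max/avg maps — plus a local skip:
   `I_{f+1} = spa(chn(conv(I_f))) + I_f`.
5. **Concatenation and fusion.**  All block outputs are concatenated to
   width `w·T` (keeps gradients flowing to early blocks) and fused by
   two 3x3 convolutions down to four channels `I_c`.
6. **Global residual learning.**  The network is trained so that `I_c`
   approximates `DWT(F − F_bic)`; the reconstruction is
   `IDWT(I_c) + F_bic`.  A 1x1 segmentation head on the fused features,
   bilinearly upsampled and softmaxed, yields per-pixel class
   probabilities.

Training minimizes a per-class soft Dice loss
`1 − Σ_l ω_l (2Σ p t + ε)/(Σ p² + Σ t² + ε)` (uniform `ω_l`, `ε = 1e-6`)
plus a reconstruction MSE term and L2 weight regularization, with Adam.
A lesion-weighted binary variant with a 1:3 prediction:truth denominator
weighting (`weighted_dice_loss`) is also provided.  All gradients are
hand-derived (im2col convolutions, attention gates, pooling, bilinear
upsampling, softmax/Dice) and verified against central finite
differences in the test suite.

## Worked example

Sixteen synthetic two-class phantoms (64x64, elliptical "tumor" on a
textured background, Gaussian noise sd 0.05) are generated and a small
network (T = 2 blocks, width 16) is overfit to them:

```r
library(sswan)

cfg <- sswan_config(num_blocks = 2, width = 16, num_classes = 2, seed = 0)
count_parameters(cfg)
#> [1] 11988

phantoms <- generate_dataset(16,
  phantom_config(size = c(64, 64), noise_sigma = 0.05), base_seed = 0)

fit <- sswan_train(phantoms, cfg, epochs = 200)
fit
#> <sswan_fit> T = 2, w = 16, 200 epochs; final loss 0.098589, mean foreground Dice 0.9761

seg <- sswan_predict(fit, phantoms[[1]]$image)
segmentation_report(seg$label_map, phantoms[[1]]$labels,
                    image_pred = seg$reconstructed,
                    image_ref = phantoms[[1]]$image)
#>   class  dice accuracy precision recall sensitivity specificity    mse psnr
#> 1     1 0.976    0.991     0.975  0.976       0.976       0.995 0.0053 24.9

sswan_evaluate(fit, phantoms)$mean_fg_dice
#> [1] 0.9762
```

The report row reads: the tumor class overlaps the truth with Dice 0.976;
99.1% of pixels are labelled correctly; and the wavelet-residual
reconstruction of this slice reaches 24.9 dB PSNR.  The training run
takes about 3 minutes on one CPU and is bit-reproducible from the seed.

## Command line

```sh
exec/sswan simulate --n 16 --size 64 --classes 2 --noise-sigma 0.05 --seed 0 --out data
exec/sswan train    --data data --epochs 200 --width 16 --blocks 2 --checkpoint ck.json
exec/sswan predict  --checkpoint ck.json --input data/sample_001_image.png --out pred.png
exec/sswan evaluate --pred pred.png --truth data/sample_001_labels.png --out metrics.tsv
```

`evaluate` accepts `--paper-exact-metrics` to switch sensitivity and
specificity to the non-standard printed convention documented in
`?classification_metrics`.

## Scope

The package operates on one 2D plane per call (multi-modal volumes can
be fed slice-by-slice or channel-stacked by the caller); multi-level
wavelet pyramids, 3D convolutions, surface metrics and external-dataset
benchmarking are out of scope.  See `vignettes/sswan-methods.Rmd` for
the full methods description, parameter choices and limitations.
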