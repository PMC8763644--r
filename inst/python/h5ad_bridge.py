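"""Convert between AnnData .h5ad files and the package's MTX directory layout.

Usage:
  python h5ad_bridge.py export <in.h5ad> <out_dir>   # h5ad -> mtx dir
  python h5ad_bridge.py import <in_dir> <out.h5ad>   # mtx dir -> h5ad
"""
import sys
import numpy as np
import scipy.sparse as sp
import scipy.io as sio
import anndata as ad
import pandas as pd
import os


def do_export(src, dst):
    a = ad.read_h5ad(src)
    os.makedirs(dst, exist_ok=True)
    X = a.X
    if not sp.issparse(X):
        X = sp.csr_matrix(np.asarray(X))
    dense_vals = X.data if X.nnz else np.array([0.0])
    integral = np.allclose(dense_vals, np.round(dense_vals))
    layer = "counts" if integral else "lognorm"
    sio.mmwrite(os.path.join(dst, "matrix.mtx"), X.T.tocoo())
    with open(os.path.join(dst, "genes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, a.var_names)) + "\n")
    with open(os.path.join(dst, "barcodes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, a.obs_names)) + "\n")
    meta = pd.DataFrame({"cell_id": a.obs_names.astype(str)})
    for col in ("study", "cell_type"):
        if col in a.obs.columns:
            meta[col] = a.obs[col].astype(str).values
    if "study" not in meta.columns:
        meta["study"] = "study1"
    meta.to_csv(os.path.join(dst, "metadata.tsv"), sep="\t", index=False)
    with open(os.path.join(dst, "layer.txt"), "w") as fh:
        fh.write(layer + "\n")


def do_import(src, dst):
    X = sio.mmread(os.path.join(src, "matrix.mtx")).T.tocsr()
    genes = [l.strip().split("\t")[0]
             for l in open(os.path.join(src, "genes.tsv")) if l.strip()]
    meta = pd.read_csv(os.path.join(src, "metadata.tsv"), sep="\t",
                       dtype=str)
    meta.index = meta["cell_id"].values
    a = ad.AnnData(X=X, obs=meta,
                   var=pd.DataFrame(index=pd.Index(genes, name="gene")))
    a.write_h5ad(dst)


if __name__ == "__main__":
    mode, src, dst = sys.argv[1:4]
    if mode == "export":
        do_export(src, dst)
    elif mode == "import":
        do_import(src, dst)
    else:
        raise SystemExit(f"unknown mode {mode}")
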