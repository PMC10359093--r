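"""Minimal single-resolution cooler (HDF5) reader/writer.

Implements the cooler v3 schema directly with h5py: groups ``chroms``,
``bins``, ``pixels`` and ``indexes`` plus the standard root attributes.
Used by the R package through tab-separated exchange files so that no R
HDF5 binding is required.

Usage:
    python cooler_io.py write OUT.cool BINS.tsv PIXELS.tsv
    python cooler_io.py read  IN.cool  BINS.tsv PIXELS.tsv

BINS.tsv:   chrom  start  end  weight   (weight 'nan' marks masked bins)
PIXELS.tsv: bin1_id  bin2_id  count     (0-based, upper triangle)
"""
import sys

import h5py
import numpy as np


def read_tsv(path):
    with open(path) as fh:
        header = fh.readline().rstrip("\n").split("\t")
        rows = [line.rstrip("\n").split("\t") for line in fh if line.strip()]
    cols = list(zip(*rows)) if rows else [[] for _ in header]
    return dict(zip(header, cols))


def write_cool(out, bins_tsv, pixels_tsv):
    bins = read_tsv(bins_tsv)
    pixels = read_tsv(pixels_tsv)
    chrom = np.array(bins["chrom"], dtype=object)
    start = np.array(bins["start"], dtype=np.int64)
    end = np.array(bins["end"], dtype=np.int64)
    weight = np.array(bins["weight"], dtype=np.float64)
    names, first = np.unique(chrom, return_index=True)
    names = names[np.argsort(first)]  # keep file order
    name_to_id = {n: i for i, n in enumerate(names)}
    chrom_id = np.array([name_to_id[c] for c in chrom], dtype=np.int32)
    lengths = np.array([end[chrom == n].max() for n in names], dtype=np.int64)

    bin1 = np.array(pixels.get("bin1_id", []), dtype=np.int64)
    bin2 = np.array(pixels.get("bin2_id", []), dtype=np.int64)
    count = np.array(pixels.get("count", []), dtype=np.float64)
    order = np.lexsort((bin2, bin1))
    bin1, bin2, count = bin1[order], bin2[order], count[order]

    n_bins = len(start)
    binsize = int(np.median(end - start)) if n_bins else 0
    str_dt = h5py.string_dtype(encoding="utf-8")
    with h5py.File(out, "w") as f:
        f.attrs["format"] = "HDF5::Cooler"
        f.attrs["format-version"] = 3
        f.attrs["bin-type"] = "fixed"
        f.attrs["bin-size"] = binsize
        f.attrs["nbins"] = n_bins
        f.attrs["nchroms"] = len(names)
        f.attrs["nnz"] = len(count)
        f.attrs["storage-mode"] = "symmetric-upper"
        g = f.create_group("chroms")
        g.create_dataset("name", data=[str(n) for n in names], dtype=str_dt)
        g.create_dataset("length", data=lengths)
        g = f.create_group("bins")
        g.create_dataset("chrom", data=chrom_id)
        g.create_dataset("start", data=start)
        g.create_dataset("end", data=end)
        g.create_dataset("weight", data=weight)
        g = f.create_group("pixels")
        g.create_dataset("bin1_id", data=bin1)
        g.create_dataset("bin2_id", data=bin2)
        g.create_dataset("count", data=count)
        g = f.create_group("indexes")
        g.create_dataset(
            "chrom_offset",
            data=np.concatenate([[0], np.cumsum(np.bincount(
                chrom_id, minlength=len(names)))]).astype(np.int64))
        g.create_dataset(
            "bin1_offset",
            data=np.concatenate([[0], np.cumsum(np.bincount(
                bin1, minlength=n_bins))]).astype(np.int64))


def read_cool(path, bins_tsv, pixels_tsv):
    with h5py.File(path, "r") as f:
        names = [n.decode() if isinstance(n, bytes) else str(n)
                 for n in f["chroms/name"][:]]
        chrom_id = f["bins/chrom"][:]
        start = f["bins/start"][:]
        end = f["bins/end"][:]
        if "weight" in f["bins"]:
            weight = f["bins/weight"][:]
        else:
            weight = np.ones(len(start))
        bin1 = f["pixels/bin1_id"][:]
        bin2 = f["pixels/bin2_id"][:]
        count = f["pixels/count"][:]
    with open(bins_tsv, "w") as fh:
        fh.write("chrom\tstart\tend\tweight\n")
        for c, s, e, w in zip(chrom_id, start, end, weight):
            fh.write(f"{names[int(c)]}\t{int(s)}\t{int(e)}\t{float(w)!r}\n")
    with open(pixels_tsv, "w") as fh:
        fh.write("bin1_id\tbin2_id\tcount\n")
        for i, j, v in zip(bin1, bin2, count):
            fh.write(f"{int(i)}\t{int(j)}\t{float(v)!r}\n")


def main(argv):
    if len(argv) != 5 or argv[1] not in {"read", "write"}:
        sys.stderr.write(__doc__)
        return 2
    if argv[1] == "write":
        write_cool(argv[2], argv[3], argv[4])
    else:
        read_cool(argv[2], argv[3], argv[4])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
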