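"""Image codec helper for the herbqc R package.

Reads a JSON task list and encodes/decodes images with Pillow:
  encode: TIFF -> lossless JPEG 2000 (reversible transform) + JPEG (quality, dpi)
  decode: JP2  -> uncompressed TIFF

Usage: python derivatives.py TASKS.json RESULT.json
"""
import json
import sys

from PIL import Image

Image.MAX_IMAGE_PIXELS = None


def run(task):
    op = task["op"]
    if op == "encode":
        im = Image.open(task["src"])
        im.load()
        if im.mode != "RGB":
            im = im.convert("RGB")
        if task.get("jp2"):
            im.save(task["jp2"], irreversible=False)
        if task.get("jpg"):
            ppi = int(task.get("ppi", 0))
            kw = {"quality": int(task.get("quality", 85))}
            if ppi:
                kw["dpi"] = (ppi, ppi)
            im.save(task["jpg"], **kw)
    elif op == "decode":
        im = Image.open(task["src"])
        im.load()
        if im.mode != "RGB":
            im = im.convert("RGB")
        im.save(task["out"], compression=None)
    else:
        raise ValueError("unknown op: %s" % op)


def main():
    with open(sys.argv[1]) as fh:
        tasks = json.load(fh)
    if isinstance(tasks, dict):
        tasks = [tasks]
    results = []
    for i, task in enumerate(tasks):
        try:
            run(task)
            results.append({"index": i, "ok": True})
        except Exception as exc:  # report, do not abort the batch
            results.append({"index": i, "ok": False, "error": str(exc)})
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
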