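# Synthetic GFP-like amino-acid sequence (239 residues).
# Generated composition loosely mimics avGFP amino-acid usage; it is NOT the
# avGFP sequence. Used as the default template for synonymous-library simulation.
MKEFVHFQITGNENTEPVPVASVMRGDRYGSLHIFGVHKQMKRMGKFKAIFGGKIEEVGNLPRKLDTPEIGQEYCGTDIYKYEDKTLILNLLFNLDEAAIWTNGVPDVLQVYHGCLDGINIVVTKQKHVDVSDFKSGSEFSALLPKIAKSDFPAKTTDYEPMTLYGYDGGVPLLLHNRSDDTVYYFEFTHDHREHDGKVPGNQNVFSNAGTSDQKNKQLGLELMNETTIGKHHHHHHYK
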