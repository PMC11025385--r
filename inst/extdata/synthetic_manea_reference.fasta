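>MANEA_ref_synthetic species=Homo sapiens synthetic reference; canonical GH99 motifs at MANEA numbering
MFLVNDGKNIHPSTRRRLQAEVVAFKAFVNERIPHFTTFTTSDTGADSTFVSCFFYIGPA
VRAMEFIRSNEIEVRVQFNHKGLRDKSRPLYTVLAYVRERKASLLNRSKASIGCMHLELT
NKGSLLTETSPPQGLGEAEFTVDQVKMKTDTVAEEPSPILEDNQAGTTRSTRCDETTIGL
SRKLSKCSYQAKKSDENGEVSQVAPRTIILEDRNGNIDLPGHIEPYDVESDWYQSTDLGY
TQATTHAWPVDQGVVNSYAAYQVLVQGVNVQTKGPKAGIDHSYVMSTRSREYGSGAAMAK
DQTGVATGVSIRDHKQGNPSNSYFLSVTVPTGGLQKAPEYLNKSEVKKIPTATLVDHEGG
IKLVGQSVPAVGLAPNALCPVSLGHPSDSGVRDLNPYGIFTIEEWHEFLCLSADALRGQE
CYLSKSILFWRSVLVEHPIQTPAPIRTNGAKIKHARKGMYVL
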